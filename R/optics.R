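#' @keywords internal
"_PACKAGE"

## Shared optical conventions for the vergence formulas.
## All refractions are spectacle-plane spherical equivalents at a 12 mm vertex;
## lengths in millimetres, powers in diopters.
.optics <- list(
  na      = 1.336,   # aqueous / vitreous refractive index
  vertex  = 12,      # spectacle vertex distance, mm
  krad    = 337.5    # keratometric radius convention: r = 337.5 / K
)

#' Thick-eye vergence refraction for a pseudophakic eye
#'
#' Solves the standard three-surface vergence equation for the spectacle-plane
#' refraction produced by an IOL of power `p_iol` sitting at the effective lens
#' position `elp` in an eye of optical axial length `lopt` with corneal radius
#' `r`.  Both SRK/T and Holladay 1 reduce to this expression; they differ only
#' in how `elp`, `lopt` and the corneal index convention `ncm1` are computed.
#'
#' @param p_iol implanted IOL power, D.
#' @param r corneal radius of curvature, mm.
#' @param elp effective lens position, mm.
#' @param lopt optical axial length, mm.
#' @param ncm1 corneal index minus one (0.333 for SRK/T, 1/3 for Holladay 1).
#' @return predicted spherical equivalent at the spectacle plane, D.
#' @keywords internal
#' @noRd
vergence_refraction <- function(p_iol, r, elp, lopt, ncm1) {
  na <- .optics$na
  v <- .optics$vertex
  n_l <- na * r - ncm1 * lopt
  n_c <- na * r - ncm1 * elp
  num <- 1000 * na * n_l - p_iol * (lopt - elp) * n_c
  den <- na * (v * n_l + lopt * r) - 0.001 * p_iol * (lopt - elp) * (v * n_c + elp * r)
  ref <- num / den
  if (any(!is.finite(ref))) {
    stop("non-finite intermediate in vergence refraction", call. = FALSE)
  }
  ref
}

## Inverse of vergence_refraction in p_iol: IOL power that yields a desired
## spectacle-plane refraction. Linear in p_iol, so the inversion is exact.
vergence_power <- function(target, r, elp, lopt, ncm1) {
  na <- .optics$na
  v <- .optics$vertex
  n_l <- na * r - ncm1 * lopt
  n_c <- na * r - ncm1 * elp
  num <- 1000 * na * (n_l - 0.001 * target * (v * n_l + lopt * r))
  den <- (lopt - elp) * (n_c - 0.001 * target * (v * n_c + elp * r))
  num / den
}

## ---- SRK/T --------------------------------------------------------------

## ELP chain of the SRK/T formula: corrected axial length, corneal width,
## corneal height, plus the published retinal-thickness correction.
srkt_geometry <- function(al, k, acd_const) {
  r <- .optics$krad / k
  lcor <- ifelse(al <= 24.2, al, -3.446 + 1.715 * al - 0.0237 * al^2)
  cw <- -5.41 + 0.58412 * lcor + 0.098 * k
  disc <- r^2 - cw^2 / 4
  clamped <- disc < 0
  h <- r - sqrt(pmax(disc, 0))
  elp <- h + (acd_const - 3.336)
  lopt <- al + (0.65696 - 0.02029 * al)
  list(r = r, elp = elp, lopt = lopt, clamped = clamped)
}

#' SRK/T predicted refraction and emmetropic power
#'
#' Implements the SRK/T theoretical formula: corrected axial length (the long-eye
#' quadratic above 24.2 mm), corneal height from corneal width, effective lens
#' position offset from the ACD constant, retinal-thickness-corrected optical
#' axial length, and the thick-eye vergence refraction at a 12 mm vertex.
#'
#' @param al axial length, mm.
#' @param k mean keratometry, D.
#' @param acd_const SRK/T ACD constant, mm (see [convert_constant()]).
#' @param p_iol implanted IOL power, D.
#' @return `srkt_refraction()`: predicted spectacle-plane spherical equivalent,
#'   D.  `srkt_power()`: the IOL power achieving `target`, D.
#' @examples
#' p <- srkt_power(23.5, 43, convert_constant(118.4, "srkt_acd"))
#' srkt_refraction(23.5, 43, convert_constant(118.4, "srkt_acd"), p) # ~0
#' @export
srkt_refraction <- function(al, k, acd_const, p_iol) {
  g <- srkt_geometry(al, k, acd_const)
  vergence_refraction(p_iol, g$r, g$elp, g$lopt, ncm1 = 0.333)
}

#' @rdname srkt_refraction
#' @param target desired postoperative refraction, D (default emmetropia).
#' @export
srkt_power <- function(al, k, acd_const, target = 0) {
  g <- srkt_geometry(al, k, acd_const)
  vergence_power(target, g$r, g$elp, g$lopt, ncm1 = 0.333)
}

## ---- Holladay 1 ---------------------------------------------------------

holladay1_geometry <- function(al, k, sf) {
  r <- .optics$krad / k
  ag <- pmin(al * 12.5 / 23.45, 13.5)
  acd <- 0.56 + r - sqrt(pmax(r^2 - ag^2 / 4, 0))
  list(r = r, elp = acd + sf, lopt = al + 0.2)
}

#' Holladay 1 predicted refraction and emmetropic power
#'
#' Holladay 1 anatomical anterior chamber depth (corneal height from the
#' capped anterior-segment width) plus the surgeon factor, optical axial
#' length AL + 0.2 mm, and the same thick-eye vergence expression as SRK/T
#' with the 4/3 corneal index convention.
#'
#' @inheritParams srkt_refraction
#' @param sf surgeon factor, mm (see [convert_constant()]).
#' @export
holladay1_refraction <- function(al, k, sf, p_iol) {
  g <- holladay1_geometry(al, k, sf)
  vergence_refraction(p_iol, g$r, g$elp, g$lopt, ncm1 = 1 / 3)
}

#' @rdname holladay1_refraction
#' @param target desired postoperative refraction, D.
#' @export
holladay1_power <- function(al, k, sf, target = 0) {
  g <- holladay1_geometry(al, k, sf)
  vergence_power(target, g$r, g$elp, g$lopt, ncm1 = 1 / 3)
}

## ---- Shammas post-LASIK (Shammas-PL) ------------------------------------

## The Shammas-PL chain: adjusted axial length L' = L - 0.1 (L - 23), lens
## plane at pACD + 0.05 mm, and an effective corneal power Kc / 1.0125.
## Spectacle refraction is moved to the corneal plane with the 12 mm vertex
## relation before entering the vergence chain.
shammas_pl_parts <- function(al, pacd) {
  list(l2 = al - 0.1 * (al - 23), c2 = pacd + 0.05)
}

#' Shammas-PL predicted refraction and emmetropic power
#'
#' The Shammas post-LASIK vergence formula: axial length adjusted toward
#' 23 mm, lens plane `pacd + 0.05` mm, corneal power `kc / 1.0125`, with the
#' target/predicted refraction vertexed between spectacle and corneal plane.
#' `kc` is the clinically derived corrected keratometry from
#' [shammas_cd_correct_k()].
#'
#' @inheritParams srkt_refraction
#' @param kc corrected corneal power, D.
#' @param pacd Shammas post-LASIK ELP constant, mm (see [convert_constant()]).
#' @export
shammas_pl_refraction <- function(al, kc, pacd, p_iol) {
  p <- shammas_pl_parts(al, pacd)
  keff <- kc / 1.0125
  w <- 1336 / (p$l2 - p$c2) - p_iol
  rc <- 1336 / (1336 / w + p$c2) - keff
  ref <- rc / (1 + 0.012 * rc)
  if (any(!is.finite(ref))) {
    stop("non-finite intermediate in Shammas-PL refraction", call. = FALSE)
  }
  ref
}

#' @rdname shammas_pl_refraction
#' @param target desired postoperative refraction, D.
#' @export
shammas_pl_power <- function(al, kc, pacd, target = 0) {
  p <- shammas_pl_parts(al, pacd)
  keff <- kc / 1.0125
  rc <- target / (1 - 0.012 * target)
  1336 / (p$l2 - p$c2) - 1336 / (1336 / (keff + rc) - p$c2)
}
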