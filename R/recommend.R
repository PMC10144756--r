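## Fixed biometric schemes of the published decision table.
recommender_k_scheme <- function() range_scheme("K", c(36, 38, 40))
recommender_al_scheme <- function() range_scheme("AL", c(26.5, 28, 29.5))

#' Built-in multi-formula recommendation tables
#'
#' The range-based formula selection rule, in two variants: one derived with
#' manufacturer lens constants (`mode = "manufacturer"`) and one with
#' constants optimized by zeroing the mean error (`mode = "optimized"`).
#' Each variant carries a 4 x 4 grid mapping (K range, AL range) to a single
#' method (`"ALMA"` or `"BARRETT_TK"`) or to the unordered pair
#' (`"ALMA/BARRETT_TK"`), plus three AL/K tie-break rows used only when a
#' grid cell names a pair (`"INCONCLUSIVE"` leaves the pair standing, in
#' which case the suggested IOL power is the average of the two methods'
#' powers).
#'
#' @param mode `"optimized"` or `"manufacturer"`.
#' @return an object of class `recommendation_table`: list with `mode`,
#'   `grid` (tibble `k_range`, `al_range`, `cell`), `alk_rows` (tibble
#'   `alk_range`, `method`), and the two fixed [range_scheme()]s.
#' @export
builtin_tables <- function(mode = c("optimized", "manufacturer")) {
  mode <- match.arg(mode)
  ks <- recommender_k_scheme()
  als <- recommender_al_scheme()
  A <- "ALMA"; B <- "BARRETT_TK"; AB <- "ALMA/BARRETT_TK"
  cells <- if (mode == "manufacturer") {
    c(B, B, B, B,
      A, AB, AB, B,
      A, A, A, AB,
      A, A, A, AB)
  } else {
    c(B, AB, A, A,
      B, AB, A, A,
      AB, A, A, AB,
      B, B, AB, B)
  }
  alk <- if (mode == "manufacturer") c(A, A, B) else c(B, "INCONCLUSIVE", A)
  structure(list(
    mode = mode,
    grid = tibble::tibble(
      k_range = rep(ks$labels, each = 4),
      al_range = rep(als$labels, times = 4),
      cell = cells),
    alk_rows = tibble::tibble(alk_range = alk_scheme()$labels, method = alk),
    k_scheme = ks, al_scheme = als
  ), class = "recommendation_table")
}

#' Per-eye formula recommendation and suggested IOL power
#'
#' Looks up each eye's (K range, AL range) cell of the selected
#' [builtin_tables()] variant.  A single-method cell decides immediately; a
#' pair cell is tie-broken by the eye's AL/K range; an inconclusive AL/K row
#' keeps the pair, and the suggested power becomes the arithmetic mean of the
#' two methods' powers for the surgeon's target refraction.
#'
#' Suggested powers for ALMA are computed internally from each eye's
#' A-constant (or an optimized constants table); Barrett True-K powers, being
#' external, must be supplied through `powers`.  Missing powers for a
#' selected method yield an error naming the eye unless `compute_power =
#' FALSE`, which returns `NA` suggested powers.
#'
#' @param cohort a validated cohort.
#' @param mode `"optimized"` or `"manufacturer"`: which decision-table
#'   variant to apply.
#' @param target surgeon's target refraction, D (default emmetropia; the
#'   recommendation layer always honors the surgeon target).
#' @param powers optional long tibble `eye_id`, `method`, `power_d` of
#'   externally computed IOL powers (required for Barrett True-K).
#' @param constants optional [optimize_constants()] table used when
#'   computing ALMA powers.
#' @param compute_power set `FALSE` to skip power suggestions.
#' @return a tibble: `eye_id`, `k_d`, `al_mm`, `alk`, `cell`, `tie_break`,
#'   `final_methods`, `suggested_power_d`, `rationale`.
#' @export
recommend <- function(cohort, mode = c("optimized", "manufacturer"),
                      target = 0, powers = NULL, constants = NULL,
                      compute_power = TRUE) {
  mode <- match.arg(mode)
  tab <- builtin_tables(mode)
  cohort <- tibble::as_tibble(cohort)
  alk <- cohort$al_mm / cohort$k_d
  k_range <- as.character(assign_range(cohort$k_d, tab$k_scheme))
  al_range <- as.character(assign_range(cohort$al_mm, tab$al_scheme))
  alk_range <- as.character(assign_range(alk, alk_scheme()))
  key <- paste(k_range, al_range)
  grid_key <- paste(tab$grid$k_range, tab$grid$al_range)
  cell <- tab$grid$cell[match(key, grid_key)]
  alk_pick <- tab$alk_rows$method[match(alk_range, tab$alk_rows$alk_range)]

  is_pair <- cell == "ALMA/BARRETT_TK"
  tie_break <- is_pair & alk_pick != "INCONCLUSIVE"
  final <- cell
  final[tie_break] <- alk_pick[tie_break]
  rationale <- dplyr::case_when(
    !is_pair ~ paste0("cell (", k_range, "; ", al_range, ") -> ", cell),
    tie_break ~ paste0("cell (", k_range, "; ", al_range, ") -> pair; AL/K ",
                       alk_range, " -> ", final),
    TRUE ~ paste0("cell (", k_range, "; ", al_range,
                  ") -> pair; AL/K inconclusive -> average of both powers")
  )

  suggested <- rep(NA_real_, nrow(cohort))
  if (compute_power) {
    get_power <- function(i, m) {
      if (!is.null(powers)) {
        hit <- powers$power_d[powers$eye_id == cohort$eye_id[i] & powers$method == m]
        if (length(hit) > 0) return(hit[1])
      }
      if (m %in% internal_methods()) {
        cst <- cohort$a_constant[i]
        if (!is.null(constants)) {
          opt <- constants$constant[constants$iol_model == cohort$iol_model[i] &
                                      constants$method == m]
          if (length(opt) > 0) cst <- opt[1]
        }
        return(emmetropic_power(m, cohort$al_mm[i], cohort$k_d[i], cst, target))
      }
      stop("no power available for method ", m, " on eye ", cohort$eye_id[i],
           call. = FALSE)
    }
    for (i in seq_len(nrow(cohort))) {
      suggested[i] <- if (final[i] == "ALMA/BARRETT_TK") {
        mean(c(get_power(i, "ALMA"), get_power(i, "BARRETT_TK")))
      } else {
        get_power(i, final[i])
      }
    }
  }
  tibble::tibble(
    eye_id = cohort$eye_id, k_d = cohort$k_d, al_mm = cohort$al_mm,
    alk = alk, cell = cell, tie_break = tie_break, final_methods = final,
    suggested_power_d = suggested, rationale = rationale
  )
}
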