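#' Chlorophyll a by the monochromatic (Lorenzen) method
#'
#' Chlorophyll a from ethanol-extract absorbances at 665 nm measured before
#' and after acidification, with 750 nm turbidity correction:
#'
#' `chl a (ug/L) = 26.7 * ((A665_b - A750_b) - (A665_a - A750_a)) * v_extract
#'   / (v_filtered * path_length)`
#'
#' Acidification converts chlorophyll a to phaeophytin, so the drop in
#' turbidity-corrected 665 nm absorbance isolates the acid-labile chlorophyll
#' signal. Negative results (noise on blank samples) are clipped to zero and
#' flagged. Phaeopigments are not reported.
#'
#' @param chla A data frame with columns `a665_before`, `a750_before`,
#'   `a665_after`, `a750_after` (absorbance units), `v_extract` (mL),
#'   `v_filtered` (L), `path_length` (cm), and optionally `sample_id` and
#'   `replicate_id`.
#' @return The input tibble plus `chla` (ug/L, >= 0) and logical
#'   `clipped_negative`.
#' @examples
#' lorenzen_chla(data.frame(
#'   a665_before = 0.050, a750_before = 0, a665_after = 0.030, a750_after = 0,
#'   v_extract = 10, v_filtered = 0.5, path_length = 1
#' ))$chla  # 10.68
#' @export
lorenzen_chla <- function(chla) {
  needed <- c("a665_before", "a750_before", "a665_after", "a750_after",
              "v_extract", "v_filtered", "path_length")
  missing_cols <- setdiff(needed, names(chla))
  if (length(missing_cols) > 0) {
    rlang::abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (any(chla$v_extract <= 0 | chla$v_filtered <= 0 | chla$path_length <= 0)) {
    rlang::abort("volumes and path length must be > 0")
  }
  if (any(chla[needed[1:4]] < 0)) {
    rlang::abort("absorbances must be >= 0")
  }
  raw <- 26.7 *
    ((chla$a665_before - chla$a750_before) -
       (chla$a665_after - chla$a750_after)) *
    chla$v_extract / (chla$v_filtered * chla$path_length)
  tibble::as_tibble(chla) |>
    dplyr::mutate(chla = pmax(raw, 0), clipped_negative = raw < 0)
}

#' Summarise chlorophyll-a replicates
#'
#' Mean and SD of replicate chlorophyll-a determinations per sample; field
#' protocols run triplicates with a mean precision near 0.3 ug/L.
#'
#' @param chla_results Output of [lorenzen_chla()] including a `sample_id`
#'   column.
#' @return A tibble with one row per sample: `chla_mean`, `chla_sd`,
#'   `n_replicates`.
#' @export
chla_summary <- function(chla_results) {
  if (!"sample_id" %in% names(chla_results)) {
    rlang::abort("chla_summary needs a sample_id column")
  }
  chla_results |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      chla_mean = mean(.data$chla),
      chla_sd = stats::sd(.data$chla),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}
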