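#' Top-3 reference normalization of peptide areas
#'
#' Normalizes the extracted-ion areas of a peptide's modification forms
#' (e.g. unmodified, singly and doubly acetylated) by the summed areas of
#' the three most intense unmodified reference peptides of the same protein,
#' correcting for differing protein amounts between immunoprecipitates.
#' Also reports each form's fraction of the total across forms.
#'
#' @param areas Data frame with columns `form` and `area` (one row per
#'   modification form), or a named numeric vector of areas.
#' @param reference_areas Numeric vector of the three reference-peptide
#'   areas (all > 0).
#' @return A data frame with columns `form`, `area`, `normalized`
#'   (area / sum of references) and `fraction` (area / total across forms).
#' @examples
#' ms_top3_normalize(c(unmodified = 10, single_ac = 5, double_ac = 5),
#'                   reference_areas = c(40, 35, 25))
#' @export
ms_top3_normalize <- function(areas, reference_areas) {
  if (is.numeric(areas) && !is.null(names(areas)))
    areas <- data.frame(form = names(areas), area = as.numeric(areas),
                        stringsAsFactors = FALSE)
  areas <- as.data.frame(areas)
  stopifnot(all(c("form", "area") %in% names(areas)))
  if (length(reference_areas) != 3)
    stop("exactly three reference-peptide areas are required")
  if (any(reference_areas <= 0)) stop("reference areas must be positive")
  if (any(areas$area < 0)) stop("areas must be nonnegative")
  ref_sum <- sum(reference_areas)
  tot <- sum(areas$area)
  if (tot <= 0) stop("total area across forms is zero")
  data.frame(form = areas$form, area = areas$area,
             normalized = areas$area / ref_sum,
             fraction = areas$area / tot,
             stringsAsFactors = FALSE)
}
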