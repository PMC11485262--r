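#' The thirteen diagnostic labels
#'
#' Returns the fixed, ordered label schema used throughout the package:
#' three cognitive-status labels (NC, MCI, DE) followed by ten dementia
#' etiology labels. Multiple etiologies may co-occur ("mixed dementia");
#' the three status labels are modelled as independent binary heads as well,
#' so no mutual-exclusivity constraint is imposed at prediction time.
#'
#' @return Character vector of length 13, in fixed order.
#' @export
#' @examples
#' diagnostic_labels()
diagnostic_labels <- function() {
  c("NC", "MCI", "DE",
    "AD", "LBD", "VD", "PRD", "FTD", "NPH", "SEF", "PSY", "TBI", "ODE")
}

#' @rdname diagnostic_labels
#' @export
etiology_labels <- function() {
  diagnostic_labels()[4:13]
}

#' @rdname diagnostic_labels
#' @export
status_labels <- function() {
  diagnostic_labels()[1:3]
}

n_labels <- function() 13L

# validate a label matrix: n x 13, entries in {0, 1, NA}
check_label_matrix <- function(labels) {
  if (!is.matrix(labels) || ncol(labels) != n_labels())
    stop("labels must be a matrix with 13 columns (one per diagnostic label)")
  vals <- labels[!is.na(labels)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("label entries must be 0, 1 or NA (unknown)")
  if (is.null(colnames(labels))) colnames(labels) <- diagnostic_labels()
  labels
}
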