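#' Construct a regional volume table
#'
#' Regional gray-matter volumes for a set of subjects: an S x N positive
#' matrix (subjects x regions) over a parcellation. Units are mm^3 or any
#' consistent volume unit; z-scoring removes the scale.
#'
#' @param volumes numeric S x N matrix, all entries positive, no missing
#'   values.
#' @param subjects character vector of S unique subject ids.
#' @param parc the [parcellation()] naming the N columns.
#' @return An object of class `"ndm_volume_table"`.
#' @export
volume_table <- function(volumes, subjects, parc) {
  volumes <- as.matrix(volumes)
  if (!is.numeric(volumes) || anyNA(volumes)) {
    stop("volumes must be numeric with no missing values")
  }
  if (any(volumes <= 0)) stop("all volumes must be positive")
  if (ncol(volumes) != n_regions(parc)) {
    stop(sprintf("volume table has %d regions but parcellation has %d",
                 ncol(volumes), n_regions(parc)))
  }
  subjects <- as.character(subjects)
  if (length(subjects) != nrow(volumes)) {
    stop("one subject id per row is required")
  }
  if (anyDuplicated(subjects)) stop("subject ids must be unique")
  dimnames(volumes) <- list(subjects, parc$region_name)
  structure(list(volumes = volumes, subjects = subjects, parcellation = parc),
            class = "ndm_volume_table")
}

#' @export
print.ndm_volume_table <- function(x, ...) {
  cat(sprintf("Volume table: %d subjects x %d regions\n",
              nrow(x$volumes), ncol(x$volumes)))
  invisible(x)
}

#' Read a volume table from a delimited file
#'
#' First column = subject id, remaining columns named by region (header row
#' required, order must match the parcellation). Comma- or tab-separated,
#' auto-detected.
#'
#' @param path path to the table.
#' @param parc the [parcellation()].
#' @return An `"ndm_volume_table"`.
#' @export
read_volume_table <- function(path, parc) {
  tab <- utils::read.table(path, sep = detect_sep(path), header = TRUE,
                           row.names = 1L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!identical(colnames(tab), parc$region_name)) {
    stop("region columns in ", path, " do not match the parcellation")
  }
  volume_table(as.matrix(tab), rownames(tab), parc)
}

#' Write a volume table to a delimited file
#'
#' @param vt an `"ndm_volume_table"`.
#' @param path output path.
#' @export
write_volume_table <- function(vt, path) {
  utils::write.table(vt$volumes, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Per-region control statistics for z-scoring
#'
#' Computes, for every region, the sample mean and sample standard deviation
#' (denominator n - 1) of regional volume across the healthy control cohort.
#' These are the mu and sigma of the atrophy z-score.
#'
#' @param controls an `"ndm_volume_table"` of control subjects (>= 2).
#' @return An object of class `"ndm_control_stats"`: list with `mu`, `sigma`
#'   (named length-N vectors) and `n_controls`.
#' @export
compute_control_stats <- function(controls) {
  stopifnot(inherits(controls, "ndm_volume_table"))
  v <- controls$volumes
  if (nrow(v) < 2L) stop("need at least 2 control subjects")
  mu <- colMeans(v)
  sigma <- apply(v, 2L, stats::sd)
  if (any(sigma <= 0)) {
    stop("zero control variance in region(s): ",
         paste(colnames(v)[sigma <= 0], collapse = ", "))
  }
  structure(list(mu = mu, sigma = sigma, n_controls = nrow(v)),
            class = "ndm_control_stats")
}

#' @export
print.ndm_control_stats <- function(x, ...) {
  cat(sprintf("Control stats over %d subjects, %d regions; median CV %.3f\n",
              x$n_controls, length(x$mu), stats::median(x$sigma / x$mu)))
  invisible(x)
}

#' Measured atrophy of one patient via control z-scores
#'
#' For each region the volume z-score is `z = (X - mu) / sigma`, where `X` is
#' the patient's regional volume and `mu`, `sigma` are the control mean and
#' standard deviation for that region. Volume loss gives negative z, so the
#' measured-atrophy vector used in all correlations against the (positive)
#' diffusion predictions is the negation, `y = -z`: larger y means more
#' atrophy, and a positive correlation means the model predicts the loss
#' pattern.
#'
#' @param patient_volumes length-N positive numeric vector of one patient's
#'   regional volumes.
#' @param stats an `"ndm_control_stats"`.
#' @return An object of class `"ndm_atrophy"`: list with `z` and `y = -z`
#'   (named length-N vectors).
#' @export
zscore_atrophy <- function(patient_volumes, stats) {
  stopifnot(inherits(stats, "ndm_control_stats"))
  patient_volumes <- as.numeric(patient_volumes)
  if (length(patient_volumes) != length(stats$mu)) {
    stop("patient volume vector length does not match control stats")
  }
  z <- (patient_volumes - stats$mu) / stats$sigma
  if (any(!is.finite(z))) stop("non-finite z-scores")
  names(z) <- names(stats$mu)
  structure(list(z = z, y = -z), class = "ndm_atrophy")
}

#' @export
print.ndm_atrophy <- function(x, ...) {
  cat(sprintf("Atrophy map: %d regions, max loss %.2f SD (%s)\n",
              length(x$y), max(x$y), names(x$y)[which.max(x$y)]))
  invisible(x)
}
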