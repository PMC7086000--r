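#' Define a brain parcellation
#'
#' A parcellation is the node set the diffusion model operates on: an ordered
#' list of gray-matter regions (e.g. the 82 cortical and subcortical regions of
#' the Desikan-Killiany atlas). Row order defines the internal 0-based region
#' index used throughout the package; all file I/O carries region names so that
#' external 1-based conventions never leak in.
#'
#' @param region_name character vector of unique region labels.
#' @param hemisphere character vector, one of `"left"`, `"right"`, `"midline"`
#'   per region (recycled if length 1).
#' @return An object of class `"ndm_parcellation"`: a data.frame with columns
#'   `region_id` (0-based integer), `region_name`, `hemisphere`.
#' @examples
#' parcellation(c("L.hippocampus", "R.hippocampus"), c("left", "right"))
#' @export
parcellation <- function(region_name, hemisphere = "midline") {
  region_name <- as.character(region_name)
  n <- length(region_name)
  if (n < 2L) stop("a parcellation needs at least 2 regions")
  if (anyDuplicated(region_name)) stop("region names must be unique")
  hemisphere <- rep_len(as.character(hemisphere), n)
  bad <- setdiff(unique(hemisphere), c("left", "right", "midline"))
  if (length(bad)) {
    stop("unknown hemisphere label(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(
    region_id = seq_len(n) - 1L,
    region_name = region_name,
    hemisphere = hemisphere,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ndm_parcellation", "data.frame")
  out
}

#' Read a parcellation table from a delimited file
#'
#' Expects two columns (`region_name`, `hemisphere`), comma- or tab-separated
#' (auto-detected), with a header row. Row order defines the region index.
#'
#' @param path path to the parcellation file.
#' @return An `"ndm_parcellation"` object.
#' @export
read_parcellation <- function(path) {
  tab <- utils::read.table(path, sep = detect_sep(path), header = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("parcellation file needs columns region_name, hemisphere")
  parcellation(tab[[1L]], tab[[2L]])
}

n_regions <- function(parc) nrow(parc)

#' @export
print.ndm_parcellation <- function(x, ...) {
  cat(sprintf("Parcellation: %d regions (%d left / %d right / %d midline)\n",
              nrow(x), sum(x$hemisphere == "left"),
              sum(x$hemisphere == "right"), sum(x$hemisphere == "midline")))
  invisible(x)
}

same_parcellation <- function(a, b) {
  identical(a$region_name, b$region_name)
}
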