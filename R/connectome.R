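#' Construct a structural connectome
#'
#' A connectome is a weighted undirected graph over a parcellation: an N x N
#' symmetric nonnegative matrix whose entry (i, j) summarizes white-matter
#' connectivity between regions i and j (typically the number of reconstructed
#' streamlines). The diagonal is zero.
#'
#' Matrices that are asymmetric within a small relative tolerance (as emitted
#' by tractography pipelines) are symmetrized by averaging `(W + t(W)) / 2`;
#' larger asymmetry is treated as a data error.
#'
#' @param weights numeric N x N matrix of nonnegative edge weights.
#' @param parc an [parcellation()] with N regions.
#' @param asym_tol relative asymmetry tolerance above which construction fails.
#' @return An object of class `"ndm_connectome"` with elements `weights`
#'   (dimnames set to region names) and `parcellation`.
#' @export
connectome <- function(weights, parc, asym_tol = 1e-6) {
  weights <- as.matrix(weights)
  if (!is.numeric(weights)) stop("connectome weights must be numeric")
  if (anyNA(weights)) stop("connectome weights contain missing values")
  n <- n_regions(parc)
  if (!all(dim(weights) == c(n, n))) {
    stop(sprintf("connectome is %dx%d but parcellation has %d regions",
                 nrow(weights), ncol(weights), n))
  }
  if (any(weights < 0)) stop("connectome weights must be nonnegative")
  scale <- max(abs(weights))
  if (scale > 0) {
    asym <- max(abs(weights - t(weights))) / scale
    if (asym > asym_tol) {
      stop(sprintf("connectome asymmetry %.3g exceeds tolerance %.3g",
                   asym, asym_tol))
    }
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  dimnames(weights) <- list(parc$region_name, parc$region_name)
  structure(list(weights = weights, parcellation = parc),
            class = "ndm_connectome")
}

#' @export
print.ndm_connectome <- function(x, ...) {
  w <- x$weights
  cat(sprintf("Connectome: %d regions, %d edges, weight range [%.4g, %.4g]\n",
              nrow(w), sum(w[upper.tri(w)] > 0), min(w), max(w)))
  invisible(x)
}

#' Read a connectome matrix from a delimited file
#'
#' Reads an N x N numeric matrix, comma- or tab-separated (auto-detected).
#' A first row/column of region names is accepted and checked against the
#' parcellation; a bare numeric matrix is matched to the parcellation by
#' position.
#'
#' @param path path to the matrix file.
#' @param parc the [parcellation()] the matrix must conform to.
#' @return An `"ndm_connectome"`.
#' @export
read_connectome <- function(path, parc) {
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  named <- anyNA(suppressWarnings(as.numeric(first[nzchar(first)])))
  if (named) {
    tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                             check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab)
    if (!identical(colnames(m), parc$region_name) ||
        !identical(rownames(m), parc$region_name)) {
      stop("region names in ", path, " do not match the parcellation")
    }
  } else {
    m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    dimnames(m) <- NULL
  }
  if (!is.numeric(m)) stop("non-numeric cells in connectome file ", path)
  connectome(m, parc)
}

#' Write a connectome matrix to a delimited file
#'
#' Tab-separated with region names as header row and first column, the dialect
#' [read_connectome()] accepts.
#'
#' @param conn an `"ndm_connectome"`.
#' @param path output path.
#' @export
write_connectome <- function(conn, path) {
  utils::write.table(conn$weights, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Average a set of connectomes
#'
#' The group-level template connectome is the element-wise arithmetic mean of
#' the individual control connectomes over a shared parcellation.
#'
#' @param connectomes non-empty list of `"ndm_connectome"` objects on the same
#'   parcellation.
#' @return The mean `"ndm_connectome"`.
#' @export
average_connectomes <- function(connectomes) {
  if (length(connectomes) == 0L) stop("need at least one connectome to average")
  parc <- connectomes[[1L]]$parcellation
  ok <- vapply(connectomes, function(cn) same_parcellation(cn$parcellation, parc),
               logical(1))
  if (!all(ok)) stop("connectomes are on different parcellations")
  w <- Reduce(`+`, lapply(connectomes, `[[`, "weights")) / length(connectomes)
  connectome(w, parc)
}

#' Build the graph Laplacian diffusion operator
#'
#' The Laplacian is the difference between the degree matrix and the adjacency
#' matrix, `H = D - W` with `D = diag(rowSums(W))`. Under the default
#' `"max-weight-scaled"` normalization the weights are first divided by their
#' largest entry, so that edge weights lie in `[0, 1]` and the diffusion rate
#' is commensurate with the default time grid `t = 0..19` at `alpha = 0.25`
#' whatever the raw streamline-count scale; `"combinatorial"` uses the raw
#' weights.
#'
#' The symmetric eigendecomposition of `H` is computed once at construction
#' and reused by every heat-kernel evaluation.
#'
#' @param conn an `"ndm_connectome"`.
#' @param normalization `"max-weight-scaled"` (default) or `"combinatorial"`.
#' @return An object of class `"ndm_laplacian"` with elements `H`,
#'   `normalization`, `eigenvalues`, `eigenvectors`, `parcellation`.
#' @export
graph_laplacian <- function(conn,
                            normalization = c("max-weight-scaled",
                                              "combinatorial")) {
  normalization <- match.arg(normalization)
  w <- conn$weights
  mx <- max(w)
  if (mx == 0) stop("cannot build a Laplacian from an all-zero connectome")
  if (normalization == "max-weight-scaled") w <- w / mx
  H <- diag(rowSums(w)) - w
  eig <- eigen(H, symmetric = TRUE)
  # numerical zero eigenvalues -> connected components
  ncomp <- sum(eig$values < max(eig$values, 1) * 1e-10)
  if (ncomp > 1L) {
    warning(sprintf("connectome graph has %d connected components; %s",
                    ncomp, "diffusion proceeds independently per component"))
  }
  structure(list(H = H,
                 normalization = normalization,
                 eigenvalues = pmax(eig$values, 0),
                 eigenvectors = eig$vectors,
                 parcellation = conn$parcellation),
            class = "ndm_laplacian")
}

#' @export
print.ndm_laplacian <- function(x, ...) {
  cat(sprintf("Graph Laplacian (%s): %d regions, spectral range [0, %.4g]\n",
              x$normalization, nrow(x$H), max(x$eigenvalues)))
  invisible(x)
}
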