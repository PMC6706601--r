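# Specificity and concentration-dependency validation: PCA of per-channel
# abundance profiles and balanced two-way ANOVA.

#' Build an abundance matrix from an ion-abundance table
#'
#' Rows are spectra (sample x spot), columns are channels, entries are
#' IS-normalized abundances. The IS channel (identically 1) is dropped.
#'
#' @param abundance Ion-abundance table from [spectra_to_abundance()].
#' @return Numeric matrix with row names `sample_id.spot` and channel
#'   labels as column names; row metadata in attribute `"row_info"`.
#' @export
abundance_matrix <- function(abundance) {
  ab <- abundance[abundance$group != "IS", , drop = FALSE]
  ab$row_id <- paste(ab$sample_id, ab$spot, sep = ".")
  rows <- unique(ab$row_id)
  cols <- unique(ab$channel_label)
  M <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  M[cbind(match(ab$row_id, rows), match(ab$channel_label, cols))] <-
    ab$normalized
  if (anyNA(M)) stop("abundance matrix is incomplete")
  info <- unique(ab[c("row_id", "sample_id", "spot")])
  attr(M, "row_info") <- info[match(rows, info$row_id), ]
  M
}

#' Principal component analysis of abundance profiles
#'
#' Column-centered (unscaled by default) eigendecomposition of the
#' covariance of the abundance matrix; used to check that spectra of
#' different analytes occupy distinct regions of score space. Component
#' signs follow a deterministic convention: the largest-magnitude loading
#' of each component is positive.
#'
#' @param M Numeric matrix (rows = spectra, columns = channels), at least
#'   2 x 2.
#' @param n_components Number of components to return.
#' @param scale. Scale columns to unit variance before decomposition
#'   (default `FALSE`: abundances are already on one normalized scale).
#' @return List with `scores` (rows x components), `loadings` (channels x
#'   components) and `explained_variance` (fractions over all components,
#'   first `n_components` returned with the full vector as attribute).
#' @export
pca_scores <- function(M, n_components = 2L, scale. = FALSE) {
  stopifnot(is.matrix(M), nrow(M) >= 2L, ncol(M) >= 2L)
  if (sum(apply(M, 2, stats::var)) <= 0)
    stop("constant matrix: zero variance, PCA undefined")
  p <- stats::prcomp(M, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(p$rotation))
  rot <- p$rotation
  sco <- p$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  out <- list(scores = sco[, seq_len(k), drop = FALSE],
              loadings = rot[, seq_len(k), drop = FALSE],
              explained_variance = ev[seq_len(k)])
  attr(out$explained_variance, "all") <- ev
  out
}

#' Balanced two-way ANOVA with interaction
#'
#' Classical sums-of-squares decomposition for a complete balanced design
#' (equal replicates per cell), with F tests of both main effects and the
#' interaction against the residual. Used for the concentration-dependency
#' and analyte-specificity checks of the method (response: IS-normalized
#' abundance; factors: target channel and concentration level).
#'
#' @param data Data frame containing the response and both factors.
#' @param response Name of the response column.
#' @param factor_a,factor_b Names of the two factor columns.
#' @return An `anova_table` data frame: term, df, sum_sq, mean_sq,
#'   statistic (F), p_value and significance stars (`***` p < 0.001,
#'   `**` p < 0.01, `*` p < 0.05).
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  stopifnot(is.data.frame(data),
            all(c(response, factor_a, factor_b) %in% names(data)))
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("both factors need at least 2 levels")
  counts <- table(A, B)
  if (any(counts == 0L))
    stop("incomplete design: empty cells")
  if (length(unique(as.vector(counts))) != 1L)
    stop("unbalanced design: unequal replicates per cell")
  if (counts[1] < 2L)
    stop("interaction test needs >= 2 replicates per cell")
  y <- data[[response]]
  fit <- stats::aov(y ~ A * B)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  terms[terms == "A"] <- factor_a
  terms[terms == "B"] <- factor_b
  terms[terms == "A:B"] <- paste(factor_a, factor_b, sep = ":")
  terms[terms == "Residuals"] <- "residuals"
  p <- tab[["Pr(>F)"]]
  stars <- ifelse(is.na(p), "",
                  ifelse(p < 0.001, "***",
                         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
  out <- data.frame(term = terms, df = tab[["Df"]],
                    sum_sq = tab[["Sum Sq"]], mean_sq = tab[["Mean Sq"]],
                    statistic = tab[["F value"]], p_value = p,
                    signif = stars, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}
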