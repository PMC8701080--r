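#' Confusion counts between called and true genotypes
#'
#' "Positive" means mutation present (value 1). The counts partition the
#' scope: TP + FP + TN + FN = |scope|.
#'
#' @param recovered n x m matrix in \{0,1\}.
#' @param truth n x m matrix in \{0,1\}.
#' @param scope optional index vector (or logical matrix) restricting the
#'   comparison; default is all entries.
#' @return named integer vector with elements TP, FP, TN, FN.
#' @export
confusionCounts <- function(recovered, truth, scope = NULL) {
  if (!identical(dim(recovered), dim(truth))) stop("shape mismatch")
  r <- recovered[if (is.null(scope)) TRUE else scope]
  t_ <- truth[if (is.null(scope)) TRUE else scope]
  if (length(r) == 0L) stop("degenerate scope: no entries to compare")
  c(TP = sum(r == 1 & t_ == 1), FP = sum(r == 1 & t_ == 0),
    TN = sum(r == 0 & t_ == 0), FN = sum(r == 0 & t_ == 1))
}

#' Sum of false-positive and false-negative rates (FPNR)
#'
#' \code{FP/(FP+TN) + FN/(FN+TP)}. When a class is absent from the truth
#' over the scope, the undefined rate is set to 0 with a warning.
#'
#' @inheritParams confusionCounts
#' @return scalar in [0, 2].
#' @export
fpnr <- function(recovered, truth, scope = NULL) {
  cc <- confusionCounts(recovered, truth, scope)
  negs <- cc["FP"] + cc["TN"]; poss <- cc["FN"] + cc["TP"]
  if (negs == 0 || poss == 0)
    warning("one class absent from the truth over the scope; its rate is set to 0")
  fprate <- if (negs > 0) cc[["FP"]] / negs else 0
  fnrate <- if (poss > 0) cc[["FN"]] / poss else 0
  unname(fprate + fnrate)
}

#' FPNR of the recovered matrix relative to the input matrix
#'
#' The recovered-side FPNR is computed over all entries; the input-side FPNR
#' only over observed entries (a missing entry carries no call that could be
#' wrong). Values below 1 indicate denoising gain.
#'
#' @param recovered n x m call matrix.
#' @param observed a [GenotypeMatrix-class] (the noisy input).
#' @param truth n x m clean matrix.
#' @return scalar ratio, or NA (with a warning) when the input FPNR is zero.
#' @export
fpnrRatio <- function(recovered, observed, truth) {
  stopifnot(is(observed, "GenotypeMatrix"))
  v <- observed@values
  omega <- !is.na(v)
  vObs <- v; vObs[!omega] <- 0   # values only read over omega below
  denom <- fpnr(vObs, truth, scope = omega)
  num <- fpnr(recovered, truth)
  if (denom == 0) {
    warning("input FPNR is zero; ratio not applicable")
    return(NA_real_)
  }
  num / denom
}

#' Proportion of missing entries imputed correctly
#'
#' Computed with the exact number of missing entries as denominator (equal
#' to the nominal m*n*MR whenever that product is an integer count).
#'
#' @param recovered n x m call matrix.
#' @param truth n x m clean matrix.
#' @param missing logical matrix or index set marking the missing entries
#'   (the complement of Omega).
#' @return scalar in [0, 1], or NA (with a warning) when nothing is missing.
#' @export
missingAccuracy <- function(recovered, truth, missing) {
  if (!identical(dim(recovered), dim(truth))) stop("shape mismatch")
  r <- recovered[missing]; t_ <- truth[missing]
  if (length(r) == 0L) {
    warning("no missing entries; imputation accuracy not applicable")
    return(NA_real_)
  }
  mean(r == t_)
}

#' Proportion of incorrectly recovered entries
#'
#' @param recovered n x m call matrix.
#' @param truth n x m clean matrix.
#' @return scalar in [0, 1].
#' @export
recoveryError <- function(recovered, truth) {
  if (!identical(dim(recovered), dim(truth))) stop("shape mismatch")
  mean(recovered != truth)
}

#' Adjusted Rand index
#'
#' Chance-corrected partition agreement under the permutation-model
#' expectation: \code{(Index - E[Index]) / (Max - E[Index])} on the pair
#' counts of the contingency table. Equals 1 iff the partitions are
#' identical up to relabeling; invariant to label permutation.
#'
#' @param a,b label vectors of equal length.
#' @return scalar, at most 1.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  N <- choose(sum(tab), 2)
  expected <- si * sj / N
  maxIndex <- (si + sj) / 2
  if (maxIndex == expected) return(1)   # both partitions degenerate (identical)
  (sij - expected) / (maxIndex - expected)
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information (arithmetic-mean normalization)
#'
#' \code{I(a;b) / ((H(a) + H(b)) / 2)}; 1 when both partitions are identical,
#' including the degenerate single-cluster case.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in [0, 1].
#' @export
normalizedMutualInfo <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b) / length(a)
  ha <- .entropy(rowSums(tab)); hb <- .entropy(colSums(tab))
  if (ha + hb == 0) return(1)  # two trivial (hence identical) partitions
  pi_ <- rowSums(tab); pj <- colSums(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (pi_[i] * pj[j]))
  as.numeric(mi / ((ha + hb) / 2))
}

#' V-measure
#'
#' Harmonic mean of homogeneity (1 - H(truth|pred)/H(truth)) and
#' completeness (1 - H(pred|truth)/H(pred)).
#'
#' @param pred,truth label vectors of equal length.
#' @return scalar in [0, 1].
#' @export
vMeasure <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors must have equal length")
  tab <- table(truth, pred) / length(pred)
  hC <- .entropy(rowSums(tab)); hK <- .entropy(colSums(tab))
  if (hC + hK == 0) return(1)
  hCgivenK <- 0; hKgivenC <- 0
  pk <- colSums(tab); pc <- rowSums(tab)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    p <- tab[i, j]
    if (p > 0) {
      hCgivenK <- hCgivenK - p * log(p / pk[j])
      hKgivenC <- hKgivenC - p * log(p / pc[i])
    }
  }
  hom <- if (hC == 0) 1 else 1 - hCgivenK / hC
  com <- if (hK == 0) 1 else 1 - hKgivenC / hK
  if (hom + com == 0) return(0)
  as.numeric(2 * hom * com / (hom + com))
}

#' Clustering accuracy scores against a reference partition
#'
#' @param pred predicted labels (vector or [SubcloneAssignment-class]).
#' @param truth reference labels.
#' @return list with \code{ari}, \code{nmi} and \code{v_measure}.
#' @export
clusteringScores <- function(pred, truth) {
  if (is(pred, "SubcloneAssignment")) pred <- pred@labels
  if (is(truth, "SubcloneAssignment")) truth <- truth@labels
  list(ari = adjustedRandIndex(pred, truth),
       nmi = normalizedMutualInfo(pred, truth),
       v_measure = vMeasure(pred, truth))
}

#' Full genotype-recovery report against ground truth
#'
#' Bundles the recovery metrics: FPNR of the recovered matrix (all entries),
#' FPNR of the noisy input (observed entries), their ratio, imputation
#' accuracy over the missing entries, the overall error proportion,
#' precision/recall/F1 of mutation calls and the raw confusion counts.
#'
#' @param recovered n x m call matrix.
#' @param truth n x m clean matrix.
#' @param observed a [GenotypeMatrix-class] (the noisy input).
#' @return a flat named list.
#' @export
recoveryReport <- function(recovered, truth, observed) {
  omega <- !is.na(observed@values)
  vObs <- observed@values; vObs[!omega] <- 0
  cc <- confusionCounts(recovered, truth)
  precision <- if (cc[["TP"]] + cc[["FP"]] > 0) cc[["TP"]] / (cc[["TP"]] + cc[["FP"]]) else NA_real_
  recall <- if (cc[["TP"]] + cc[["FN"]] > 0) cc[["TP"]] / (cc[["TP"]] + cc[["FN"]]) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  inputFpnr <- fpnr(vObs, truth, scope = omega)
  recFpnr <- fpnr(recovered, truth)
  macc <- if (any(!omega)) missingAccuracy(recovered, truth, !omega) else NA_real_
  list(fpnr_recovered = recFpnr,
       fpnr_input = inputFpnr,
       fpnr_ratio = if (inputFpnr > 0) recFpnr / inputFpnr else NA_real_,
       missing_accuracy = macc,
       error = recoveryError(recovered, truth),
       precision = precision, recall = recall, f1 = f1,
       TP = cc[["TP"]], FP = cc[["FP"]], TN = cc[["TN"]], FN = cc[["FN"]])
}
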