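#' Stratified k-nearest-neighbour imputation
#'
#' Replaces each missing cell by the mean of that feature over the `k`
#' nearest donor subjects within the same severity stratum. Distances are
#' Euclidean over the stratum's fully observed, standardized features.
#' When a stratum has at most `k` complete donors for a feature, the
#' stratum feature mean is used instead (with a warning). Donor statistics
#' can be restricted to training subjects via `donorIdx` to avoid leakage.
#'
#' @param table a [FeatureTable-class]
#' @param k number of neighbours (default 3)
#' @param donorIdx column indices allowed to act as donors (default: all)
#' @return The imputed table (mask all-FALSE).
#' @export
stratifiedKnnImpute <- function(table, k = 3L, donorIdx = seq_len(ncol(table))) {
  v <- featureValues(table); m <- missingMask(table)
  if (!any(m)) return(table)
  sev <- severityLabels(table)
  for (cl in unique(sev)) {
    cols <- which(sev == cl)
    donors <- intersect(cols, donorIdx)
    sub <- v[, cols, drop = FALSE]
    subM <- m[, cols, drop = FALSE]
    if (!any(subM)) next
    # features observed for every donor in the stratum: the distance space
    complete <- which(rowSums(m[, donors, drop = FALSE]) == 0)
    dv <- v[complete, donors, drop = FALSE]
    ctr <- rowMeans(dv); scl <- apply(dv, 1, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    zd <- (dv - ctr) / scl
    for (jj in seq_along(cols)) {
      missF <- which(subM[, jj])
      if (!length(missF)) next
      j <- cols[jj]
      zq <- (v[complete, j] - ctr) / scl
      obsDims <- which(!is.na(zq))
      for (f in missF) {
        cand <- donors[!is.na(v[f, donors]) & donors != j]
        if (length(cand) < max(k, 1L) || !length(obsDims)) {
          mu <- mean(v[f, donors], na.rm = TRUE)
          if (!is.finite(mu)) mu <- mean(v[f, ], na.rm = TRUE)
          warning(sprintf("stratum '%s' too small for k-NN on '%s'; stratum mean used",
                          cl, rownames(v)[f]))
          v[f, j] <- mu
        } else {
          di <- match(cand, donors)
          d2 <- colSums((zd[obsDims, di, drop = FALSE] - zq[obsDims])^2)
          nb <- cand[order(d2)[seq_len(min(k, length(cand)))]]
          v[f, j] <- mean(v[f, nb])
        }
        m[f, j] <- FALSE
      }
    }
  }
  SummarizedExperiment::assay(table, "values") <- v
  SummarizedExperiment::assay(table, "mask") <- m
  table
}

#' Plug-in mutual information between a numeric column and class labels
#'
#' Discretizes `x` into `bins` bins (equal-frequency by default) and
#' evaluates the plug-in mutual information with the labels, in bits.
#'
#' @param x numeric vector
#' @param y labels (character/factor)
#' @param bins number of bins
#' @param binning `"frequency"` (equal-frequency) or `"width"` (equal-width)
#' @return Mutual information in bits.
#' @export
mutualInformation <- function(x, y, bins = 10L, binning = c("frequency", "width")) {
  binning <- match.arg(binning)
  br <- if (binning == "frequency") {
    unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L), names = FALSE))
  } else {
    seq(min(x), max(x), length.out = bins + 1L)
  }
  if (length(br) < 2L) return(0)
  xb <- cut(x, breaks = br, include.lowest = TRUE)
  joint <- table(xb, y)
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  sel <- p > 0
  sum(p[sel] * log2(p[sel] / outer(px, py)[sel]))
}

# The four candidate per-feature scalings, in fixed preference order.
.normSchemes <- c("zscore", "robust", "meanrange", "minmax")

.fitScheme <- function(x, scheme) {
  switch(scheme,
    zscore    = list(center = mean(x), scale = stats::sd(x)),
    minmax    = list(center = min(x), scale = max(x) - min(x)),
    meanrange = list(center = mean(x), scale = max(x) - min(x)),
    robust    = list(center = stats::median(x), scale = stats::IQR(x)))
}

#' Adaptive per-feature normalization by mutual information
#'
#' For each feature, fits the four candidate scalings (z-score, min-max,
#' mean-range, robust) on the training subjects, scores each by the mutual
#' information between the scaled (discretized) feature and the severity
#' labels, and keeps the argmax; ties break by the fixed preference order
#' z-score > robust > mean-range > min-max. (With equal-frequency binning
#' the four monotone schemes tie by construction; equal-width binning makes
#' them differ.) Fitted parameters are stored in `metadata(x)$norm_meta`
#' and applied to every subject, so held-out columns are transformed with
#' training statistics only.
#'
#' @param table an imputed [FeatureTable-class]
#' @param trainIdx column indices to fit on (default: all)
#' @param bins,binning passed to [mutualInformation()]
#' @return The normalized table with `norm_meta` populated.
#' @export
adaptiveNormalize <- function(table, trainIdx = seq_len(ncol(table)),
                              bins = 10L, binning = "frequency") {
  if (any(missingMask(table))) stop("normalize after imputation")
  v <- featureValues(table)
  y <- severityLabels(table)[trainIdx]
  meta <- vector("list", nrow(v)); names(meta) <- rownames(v)
  for (f in seq_len(nrow(v))) {
    xt <- v[f, trainIdx]
    if (stats::sd(xt) == 0 || diff(range(xt)) == 0) {
      meta[[f]] <- list(scheme = "none", center = 0, scale = 1, flagged = TRUE)
      next
    }
    mi <- vapply(.normSchemes, function(s) {
      p <- .fitScheme(xt, s)
      if (!is.finite(p$scale) || p$scale == 0) return(-Inf)
      mutualInformation((xt - p$center) / p$scale, y, bins = bins, binning = binning)
    }, numeric(1))
    best <- .normSchemes[which.max(mi)]   # which.max takes the first = preference order
    p <- .fitScheme(xt, best)
    meta[[f]] <- list(scheme = best, center = p$center, scale = p$scale,
                      mi = mi[[best]], flagged = FALSE)
    v[f, ] <- (v[f, ] - p$center) / p$scale
  }
  SummarizedExperiment::assay(table, "values") <- v
  metadata(table)$norm_meta <- meta
  table
}

#' Apply stored normalization parameters to a table
#'
#' @param table an imputed [FeatureTable-class]
#' @param normMeta `metadata(x)$norm_meta` from a fitted table
#' @return The transformed table (row-wise, using only stored parameters).
#' @export
applyNormalization <- function(table, normMeta) {
  v <- featureValues(table)
  for (f in rownames(v)) {
    p <- normMeta[[f]]
    if (is.null(p) || p$scheme == "none") next
    v[f, ] <- (v[f, ] - p$center) / p$scale
  }
  SummarizedExperiment::assay(table, "values") <- v
  metadata(table)$norm_meta <- normMeta
  table
}

#' Design matrix for modelling
#'
#' @param table a [FeatureTable-class]
#' @param features feature names (rows) to include
#' @param subjects column indices/names to include
#' @return Numeric matrix, subjects x features.
#' @export
designMatrix <- function(table, features = rownames(table),
                         subjects = seq_len(ncol(table))) {
  t(featureValues(table)[features, subjects, drop = FALSE])
}
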