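#' mRMR feature selection (FCQ scheme)
#'
#' Greedy maximum-relevance minimum-redundancy selection supervised by the
#' binary event indicator. Relevance of a feature is the one-way ANOVA
#' F-statistic of the feature against the two event groups; redundancy is
#' the mean absolute Pearson correlation with the already-selected set; at
#' each step the feature maximising the quotient F / redundancy is added
#' (the first pick maximises F alone). Constant features are excluded with
#' a warning before selection.
#'
#' @param features data.frame or matrix of numeric features (an `id` column
#'   is dropped); no NaN allowed.
#' @param events 0/1 event indicator, one per row.
#' @param k number of features to return.
#' @return Character vector of `k` feature names in selection order.
#' @export
mrmr_select <- function(features, events, k = 50) {
  x <- as.data.frame(features)
  x$id <- NULL
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) stop("features must be numeric with no NA/NaN")
  events <- as.integer(events)
  stopifnot(length(events) == nrow(x), all(events %in% 0:1))
  if (length(unique(events)) < 2)
    stop("both event groups must be present for mRMR relevance")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant feature(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  p <- ncol(x)
  if (k > p) stop("k = ", k, " exceeds the ", p, " usable features")

  # two-group ANOVA F statistic, vectorised over columns
  n <- nrow(x); n1 <- sum(events == 1); n0 <- n - n1
  m1 <- colMeans(x[events == 1, , drop = FALSE])
  m0 <- colMeans(x[events == 0, , drop = FALSE])
  gm <- colMeans(x)
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ssw <- colSums((t(t(x[events == 1, , drop = FALSE]) - m1))^2) +
         colSums((t(t(x[events == 0, , drop = FALSE]) - m0))^2)
  Fstat <- ssb / (ssw / (n - 2))
  Fstat[!is.finite(Fstat)] <- 0

  cmat <- abs(stats::cor(x))
  sel <- integer(0)
  avail <- seq_len(p)
  for (step in seq_len(k)) {
    if (length(sel) == 0) {
      pick <- avail[which.max(Fstat[avail])]
    } else {
      red <- rowMeans(cmat[avail, sel, drop = FALSE])
      red <- pmax(red, 1e-12)
      pick <- avail[which.max(Fstat[avail] / red)]
    }
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
  }
  colnames(x)[sel]
}
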