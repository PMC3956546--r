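#' Pearson correlation distance between samples
#'
#' Sample-to-sample distance used for expression and drug-score
#' clustering: \eqn{d(i,j) = 1 - r(i,j)} with \eqn{r} the Pearson
#' correlation of the two samples' feature vectors, so identical profiles
#' are at distance 0, uncorrelated ones at 1, perfectly anticorrelated
#' ones at 2.
#'
#' @param x numeric matrix, features x samples (column names are sample
#'   ids).
#' @return Symmetric distance matrix with zero diagonal, entries in
#'   [0, 2].
#' @examples
#' m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
#' pearsonDistance(m)
#' @export
pearsonDistance <- function(x) {
    x <- as.matrix(x)
    if (ncol(x) < 2L || nrow(x) < 2L)
        stop("need at least 2 samples and 2 features")
    v <- apply(x, 2L, sd)
    if (any(v == 0))
        stop("zero-variance sample(s): ",
             paste(colnames(x)[v == 0], collapse = ", "))
    d <- 1 - cor(x)
    diag(d) <- 0
    d
}

#' Classical multidimensional scaling
#'
#' Torgerson's classical MDS: double-center \eqn{-\tfrac12 D^2},
#' eigendecompose, and use the top-k eigenvectors scaled by the square
#' roots of their (non-negative) eigenvalues as coordinates.  Negative
#' eigenvalues (possible for non-Euclidean distances such as correlation
#' distance) are truncated.  Because eigenvectors are sign-arbitrary, each
#' axis is oriented so that its largest-magnitude coordinate is positive,
#' making the embedding deterministic.
#'
#' @param D symmetric distance matrix with sample ids as dimnames.
#' @param k number of dimensions (default 2).
#' @return List: \code{points} (samples x k coordinate matrix, columns
#'   centered), \code{eig} (all eigenvalues, non-increasing).
#' @examples
#' xy <- matrix(rnorm(20), 10, 2)
#' D <- as.matrix(dist(xy))
#' emb <- classicalMDS(D, k = 2)
#' @export
classicalMDS <- function(D, k = 2L) {
    D <- as.matrix(D)
    n <- nrow(D)
    if (k < 1L || k > n - 1L) stop("k must be in [1, n-1]")
    fit <- cmdscale(as.dist(D), k = k, eig = TRUE)
    if (all(fit$eig <= 1e-12)) stop("no positive eigenvalues")
    pts <- fit$points
    if (ncol(pts) < k) {
        # cmdscale returns fewer axes when eigenvalues are non-positive
        pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
    }
    for (a in seq_len(ncol(pts))) {
        mx <- which.max(abs(pts[, a]))
        if (pts[mx, a] < 0) pts[, a] <- -pts[, a]
    }
    colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
    list(points = pts, eig = fit$eig)
}

#' Cluster separation by mean silhouette width
#'
#' Quantifies how well an embedding separates labeled groups: the mean
#' silhouette width over samples, using Euclidean distance in the
#' embedding.  Values near +1 indicate tight, well-separated clusters;
#' values near 0 indicate no structure beyond chance.
#'
#' @param coords samples x dimensions coordinate matrix.
#' @param labels group label per sample (>= 2 distinct labels).
#' @return Mean silhouette width (scalar).
#' @export
clusterSeparation <- function(coords, labels) {
    coords <- as.matrix(coords)
    labels <- as.character(labels)
    stopifnot(length(labels) == nrow(coords))
    if (length(unique(labels)) < 2L)
        stop("need at least 2 distinct labels")
    sil <- cluster::silhouette(as.integer(factor(labels)),
                               dist(coords))
    mean(sil[, "sil_width"])
}

#' Drug-score matrix for cohort clustering
#'
#' Builds the drugs x samples matrix of summary scores from a list of
#' reports; drugs a sample's report does not rank get score 0.
#'
#' @param reports list of \code{\linkS4class{PMedReport}} objects.
#' @return Numeric matrix, drugs x samples.
#' @export
drugScoreMatrix <- function(reports) {
    drugs <- sort(unique(unlist(lapply(reports,
        function(r) reportSummary(r)$drug))))
    samples <- vapply(reports, sampleId, character(1L))
    m <- matrix(0, length(drugs), length(samples),
                dimnames = list(drugs, samples))
    for (r in reports) {
        s <- reportSummary(r)
        if (nrow(s)) m[s$drug, sampleId(r)] <- s$score
    }
    m
}
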