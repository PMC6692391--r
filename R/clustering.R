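# Subtype discovery for trait-associated loci: hierarchical clustering on
# locus x trait z-scores with iterative silhouette-based outlier removal,
# and semantic labelling of the two clusters as sleep propensity vs sleep
# fragmentation.

#' Pairwise Euclidean distances between loci
#'
#' `D[i, j] = sqrt(sum_k (x[i, k] - x[j, k])^2)` over the trait z-scores;
#' the z-scores enter raw (not column-standardised).
#'
#' @param x numeric matrix, loci as rows and trait z-scores as columns.
#' @return symmetric distance matrix with zero diagonal and the row names
#'   of `x`.
#' @export
pairwise_distance <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two loci")
  if (!all(is.finite(x))) stop("z-scores must be finite")
  as.matrix(stats::dist(x, method = "euclidean"))
}

#' Agglomerative hierarchical clustering cut into k groups
#'
#' @param d symmetric distance matrix (e.g. from [pairwise_distance]).
#' @param k number of clusters (default 2).
#' @param linkage agglomeration criterion: `"complete"` (default),
#'   `"average"`, `"single"`, or `"ward.D2"`.
#' @return integer cluster labels in 1..k, named by locus.
#' @export
hierarchical_cluster <- function(d, k = 2,
                                 linkage = c("complete", "average",
                                             "single", "ward.D2")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  if (k > nrow(d)) stop("k cannot exceed the number of loci")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  stats::cutree(hc, k = k)
}

#' Silhouette coefficients
#'
#' For locus i with mean within-cluster distance `a_i` (excluding itself)
#' and `b_i` the smallest mean distance to any other cluster,
#' `s_i = (b_i - a_i) / max(a_i, b_i)`; values near +1 indicate the locus
#' sits well inside its cluster, negative values that it is likely
#' misassigned. A locus alone in its cluster gets `s_i = 0` by convention.
#'
#' @param d symmetric distance matrix.
#' @param labels cluster assignment per locus (at least two nonempty
#'   clusters).
#' @return list with `widths` (per-locus coefficients, named) and
#'   `average`.
#' @export
silhouette_widths <- function(d, labels) {
  d <- as.matrix(d)
  stopifnot(length(labels) == nrow(d))
  cl <- unique(labels)
  if (length(cl) < 2L) stop("silhouettes need at least two clusters")
  s <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(cl[cl != labels[i]],
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  names(s) <- rownames(d)
  list(widths = s, average = mean(s))
}

#' Iterative silhouette-based outlier removal
#'
#' Clusters the loci, computes silhouette coefficients, removes every
#' locus with a negative coefficient (they are likely misclustered),
#' reclusters, and repeats until all coefficients are positive or
#' `max_iter` is reached. The full per-iteration audit trail is retained.
#'
#' @param x locus x trait z-score matrix (at least 4 loci).
#' @param k number of clusters (default 2).
#' @param linkage agglomeration criterion, see [hierarchical_cluster].
#' @param max_iter iteration cap (default 10).
#' @return Object of class `subtype_clustering`: list with
#'   `retained` / `removed` locus IDs, integer `labels` for retained loci,
#'   `subtype` (semantic labels from [label_clusters] when `k == 2`),
#'   `iterations` (per-iteration labels, silhouettes, average silhouette,
#'   removed loci), `converged`, and `linkage`.
#' @export
iterative_outlier_removal <- function(x, k = 2, linkage = "complete",
                                      max_iter = 10) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("locus_%02d",
                                                   seq_len(nrow(x)))
  if (nrow(x) < 4L) stop("need at least four loci")
  keep <- rownames(x)
  iterations <- list()
  converged <- FALSE
  labels <- NULL
  for (it in seq_len(max_iter)) {
    if (length(keep) < k + 1L) {
      warning("fewer than k + 1 loci remain; returning partial result")
      break
    }
    d <- pairwise_distance(x[keep, , drop = FALSE])
    labels <- hierarchical_cluster(d, k = k, linkage = linkage)
    sil <- silhouette_widths(d, labels)
    neg <- names(sil$widths)[sil$widths < 0]
    iterations[[it]] <- list(iteration = it, loci = keep,
                             labels = labels,
                             silhouette = sil$widths,
                             average_silhouette = sil$average,
                             removed = neg)
    if (length(neg) == 0L) { converged <- TRUE; break }
    keep <- setdiff(keep, neg)
  }
  subtype <- NULL
  if (!is.null(labels) && k == 2) {
    subtype <- label_clusters(x[names(labels), , drop = FALSE], labels)
  }
  structure(list(retained = names(labels), removed = setdiff(rownames(x),
                                                             names(labels)),
                 labels = labels, subtype = subtype,
                 iterations = iterations, converged = converged,
                 n_iter = length(iterations), linkage = linkage, k = k),
            class = "subtype_clustering")
}

#' Label two clusters as sleep propensity vs sleep fragmentation
#'
#' Cluster centroids are scored against the sleep-propensity sign template
#' (+, +, -, -) over (efficiency, duration, bouts, insomnia): sleepiness
#' risk alleles associated with higher efficiency, longer sleep, fewer
#' bouts and fewer insomnia symptoms. A cluster whose centroid matches at
#' least 3 of the 4 template signs is labelled `propensity` and the other
#' `fragmentation`; if both or neither reach 3/4, labels go to the cluster
#' with the greater total sign agreement, and an exact tie is flagged via
#' the `tie` attribute.
#'
#' @param x z-score matrix of the labelled loci (columns in the fixed
#'   trait order).
#' @param labels integer cluster assignment with exactly two clusters.
#' @return named character vector mapping each locus to `"propensity"` or
#'   `"fragmentation"`; cluster-level labels in the `cluster_labels`
#'   attribute.
#' @export
label_clusters <- function(x, labels) {
  x <- as.matrix(x)
  cl <- sort(unique(labels))
  if (length(cl) != 2L) stop("semantic labelling expects exactly 2 clusters")
  tmpl <- propensity_template
  agree <- vapply(cl, function(g) {
    centroid <- colMeans(x[labels == g, , drop = FALSE])
    if (all(centroid == 0)) warning("degenerate all-zero cluster centroid")
    sum(sign(centroid) == tmpl)
  }, numeric(1))
  hits <- agree >= 3
  tie <- FALSE
  if (sum(hits) == 1L) {
    prop <- cl[hits]
  } else {
    tie <- agree[1L] == agree[2L]
    if (tie) warning("ambiguous cluster labelling: equal template ",
                     "agreement; assigning by cluster order")
    prop <- cl[which.max(agree)]
  }
  out <- ifelse(labels == prop, "propensity", "fragmentation")
  names(out) <- names(labels)
  attr(out, "cluster_labels") <- stats::setNames(
    ifelse(cl == prop, "propensity", "fragmentation"), cl)
  attr(out, "tie") <- tie
  out
}

#' @export
print.subtype_clustering <- function(x, ...) {
  cat(sprintf(
    "<subtype_clustering> %s linkage, k = %d: %d iteration(s), %s\n",
    x$linkage, x$k, x$n_iter,
    if (x$converged) "converged" else "not converged"))
  cat(sprintf("  retained %d loci, removed %d (%s)\n", length(x$retained),
              length(x$removed),
              if (length(x$removed)) paste(x$removed, collapse = ", ")
              else "none"))
  if (!is.null(x$subtype)) print(table(x$subtype))
  invisible(x)
}

#' Write the per-iteration clustering audit trail as JSON
#'
#' @param result a `subtype_clustering` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_cluster_audit <- function(result, path) {
  stopifnot(inherits(result, "subtype_clustering"))
  audit <- list(
    linkage = result$linkage, k = result$k,
    converged = result$converged, n_iter = result$n_iter,
    removed = result$removed,
    subtype = as.list(stats::setNames(as.character(result$subtype),
                                      names(result$subtype))),
    iterations = lapply(result$iterations, function(it) {
      list(iteration = it$iteration,
           average_silhouette = it$average_silhouette,
           removed = it$removed,
           silhouette = as.list(it$silhouette),
           labels = as.list(it$labels))
    })
  )
  jsonlite::write_json(audit, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
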