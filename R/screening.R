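# Two-stage temporal biomarker screen: broad Hyper/Hypo categorization of
# differential transcripts, fuzzy c-means sub-clustering of time profiles,
# consistency selection, and cross-stage intersection.

#' Assign a broad temporal category from per-timepoint differential statuses
#'
#' A transcript is `Hyper` when it is hyper-methylated at one or more
#' timepoints and never hypo-methylated, `Hypo` symmetrically, and
#' `Inconsistent` when both directions occur (such transcripts are removed
#' from further screening); `None` when no timepoint is differential.
#'
#' @param statuses Character vector of per-timepoint statuses
#'   (`"hyper"`, `"hypo"`, `"ns"`), or a gene-by-timepoint matrix of them.
#' @return A single category, or a named vector of categories for a matrix.
#' @export
assign_category <- function(statuses) {
  if (is.matrix(statuses)) {
    if (ncol(statuses) < 1L) stop("empty status vector")
    has_hyper <- rowSums(statuses == "hyper") > 0
    has_hypo <- rowSums(statuses == "hypo") > 0
    out <- ifelse(has_hyper & has_hypo, "Inconsistent",
                  ifelse(has_hyper, "Hyper",
                         ifelse(has_hypo, "Hypo", "None")))
    names(out) <- rownames(statuses)
    return(out)
  }
  if (length(statuses) < 1L) stop("empty status vector")
  bad <- setdiff(unique(statuses), c("hyper", "hypo", "ns"))
  if (length(bad)) stop("unknown status: ", paste(bad, collapse = ", "))
  has_hyper <- any(statuses == "hyper")
  has_hypo <- any(statuses == "hypo")
  if (has_hyper && has_hypo) "Inconsistent"
  else if (has_hyper) "Hyper"
  else if (has_hypo) "Hypo"
  else "None"
}

# Row standardization. "center" (default) subtracts the row mean only, so a
# temporally flat profile maps near the origin and stays recognizable as its
# own shape class; "z" additionally divides by the row sd, which projects
# every profile onto a sphere and turns flat-plus-noise profiles into pure
# noise directions (they then scatter instead of clustering). Constant rows
# standardize to the zero vector, with a warning under "z" where the scale
# is undefined.
.standardize_profiles <- function(x, scale = c("center", "z")) {
  scale <- match.arg(scale)
  mu <- rowMeans(x)
  if (scale == "center") return(x - mu)
  sdv <- apply(x, 1, stats::sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " constant profile(s) standardized to the zero vector")
    sdv[zero] <- 1
  }
  (x - mu) / sdv
}

#' Fuzzy c-means clustering of temporal log-fold-change profiles
#'
#' Profiles are standardized per gene — mean-centered by default, optionally
#' full z-scored via `scale = "z"` — and partitioned by fuzzy c-means with
#' Euclidean distance:
#' memberships \eqn{u_{ij} \propto (1/d_{ij}^2)^{1/(m-1)}} normalized to sum
#' to 1 per gene, centroids the membership\eqn{^m}-weighted means. The
#' objective \eqn{\sum_{ij} u_{ij}^m d_{ij}^2} is non-increasing across
#' iterations. Genes coinciding with several centroids (or all-identical
#' inputs) receive equal memberships over the tied clusters. Hard assignment
#' is the maximal membership, ties broken by lowest cluster index.
#'
#' @param profiles Gene-by-timepoint numeric matrix of log2 fold changes
#'   (rownames are gene ids).
#' @param n_clusters Number of clusters (default 2 sub-categories).
#' @param fuzzifier Fuzziness exponent m > 1 (default 2).
#' @param seed Integer seed for the random initial memberships.
#' @param scale Per-gene standardization: `"center"` (default, subtract the
#'   row mean) or `"z"` (also divide by the row sd). Centering keeps
#'   temporally flat profiles together as their own shape class; full
#'   z-scoring maps them to arbitrary noise directions.
#' @param max_iter,tol Iteration cap and relative objective tolerance.
#' @return List of class `fuzzy_clust`: `membership` (gene x cluster),
#'   `hard` (named integer vector), `centroids` (cluster x timepoint,
#'   standardized scale), `objective` trace, `n_clusters`, `seed`.
#' @export
cluster_time_profiles <- function(profiles, n_clusters = 2, fuzzifier = 2,
                                  seed = 1L, scale = "center",
                                  max_iter = 200, tol = 1e-10) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < n_clusters) stop("fewer genes than clusters")
  if (ncol(profiles) < 2) stop("need >= 2 timepoints")
  if (fuzzifier <= 1) stop("fuzzifier must exceed 1")
  z <- .standardize_profiles(profiles, scale = scale)
  n <- nrow(z); k <- n_clusters
  set.seed(seed)
  u <- matrix(stats::runif(n * k), n, k)
  u <- u / rowSums(u)
  expo <- 2 / (fuzzifier - 1)
  obj <- numeric(0)
  for (iter in seq_len(max_iter)) {
    um <- u^fuzzifier
    cent <- (t(um) %*% z) / colSums(um)
    # squared Euclidean distances gene x cluster
    d2 <- outer(rowSums(z^2), rep(1, k)) - 2 * z %*% t(cent) +
      outer(rep(1, n), rowSums(cent^2))
    d2 <- pmax(d2, 0)
    obj <- c(obj, sum(um * d2))
    zero <- d2 < 1e-300
    inv <- (1 / pmax(d2, 1e-300))^(expo / 2)
    u_new <- inv / rowSums(inv)
    tie <- rowSums(zero) > 0
    if (any(tie)) {
      u_new[tie, ] <- zero[tie, , drop = FALSE] / rowSums(zero[tie, , drop = FALSE])
    }
    # all-identical degenerate case: every distance equal -> uniform split
    flat <- apply(d2, 1, function(r) max(r) - min(r) < 1e-12)
    if (any(flat)) u_new[flat, ] <- 1 / k
    delta <- max(abs(u_new - u))
    u <- u_new
    if (length(obj) > 1 &&
        abs(diff(utils::tail(obj, 2))) <= tol * max(obj[1], 1) &&
        delta < 1e-8) break
  }
  um <- u^fuzzifier
  cent <- (t(um) %*% z) / colSums(um)
  hard <- max.col(u, ties.method = "first")
  names(hard) <- rownames(profiles)
  rownames(u) <- rownames(profiles)
  structure(list(membership = u, hard = hard, centroids = cent,
                 objective = obj, n_clusters = k, fuzzifier = fuzzifier,
                 scale = scale, seed = as.integer(seed)),
            class = "fuzzy_clust")
}

#' Select the consistently responding sub-category
#'
#' Among the clusters of a category's time profiles, keeps the genes
#' hard-assigned to cluster(s) whose mean unstandardized profile keeps the
#' category's sign at every timepoint (for `Hyper`: the minimum over
#' timepoints of the cluster's mean log2 fold change is positive; for
#' `Hypo` the maximum is negative). Sign consistency is judged on the raw
#' mean profile because z-scoring destroys sign information. If several
#' clusters qualify (e.g. the consistent set was split), their union is
#' returned; if none qualifies, the empty set.
#'
#' @param profiles The gene-by-timepoint log2 fold-change matrix that was
#'   clustered (raw, unstandardized).
#' @param cluster_result A `fuzzy_clust` from [cluster_time_profiles()].
#' @param category `"Hyper"` or `"Hypo"`.
#' @return Character vector of gene ids (possibly empty).
#' @export
select_consistent <- function(profiles, cluster_result, category = c("Hyper", "Hypo")) {
  category <- match.arg(category)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != length(cluster_result$hard) ||
      !identical(rownames(profiles), names(cluster_result$hard))) {
    stop("cluster_result does not match profiles")
  }
  keep <- character(0)
  for (cl in seq_len(cluster_result$n_clusters)) {
    members <- names(cluster_result$hard)[cluster_result$hard == cl]
    if (!length(members)) next
    mp <- colMeans(profiles[members, , drop = FALSE])
    ok <- if (category == "Hyper") min(mp) > 0 else max(mp) < 0
    if (ok) keep <- c(keep, members)
  }
  unique(keep)
}

#' Intersect candidate gene sets across screening stages
#'
#' @param sets Named list (>= 2 entries) of character vectors of gene ids.
#' @param require_all If `TRUE` (default) the candidate set is the exact
#'   intersection of all sets; if `FALSE`, genes present in at least two
#'   sets qualify.
#' @return List of class `candidate_set`: `genes` (sorted) and `provenance`
#'   (the contributing set names).
#' @export
intersect_candidates <- function(sets, require_all = TRUE) {
  if (length(sets) < 2) stop("need at least two sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  sets <- lapply(sets, unique)
  if (require_all) {
    genes <- Reduce(intersect, sets)
  } else {
    tab <- table(unlist(sets))
    genes <- names(tab)[tab >= 2]
  }
  structure(list(genes = sort(genes), provenance = names(sets)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set:", length(x$genes), "gene(s) from",
      paste(x$provenance, collapse = " ∩ "), "\n")
  if (length(x$genes)) cat(" ", paste(utils::head(x$genes, 20), collapse = ", "),
                           if (length(x$genes) > 20) "..." else "", "\n")
  invisible(x)
}

#' Run the two-stage temporal biomarker screen
#'
#' Stage I: per-timepoint differential m6A calls against sham, broad
#' categorization (transcripts with both directions are dropped as
#' inconsistent), fuzzy c-means sub-clustering of each category's time
#' profiles, and selection of the consistently responding sub-category.
#' Stage II: the single-timepoint hyper sets at two anchor timepoints
#' (defaults: the earliest timepoint and the peak-response day, 1 and 14).
#' The candidate set is the intersection of the consistent stage-I set with
#' both stage-II sets.
#'
#' @param mat An `m6a_matrix` from [m6a_level_matrix()].
#' @param stage2_tps Two anchor timepoints (days) for stage II; defaults to
#'   `c(1, 14)` intersected with the design's timepoints.
#' @param n_clusters,fuzzifier,seed Clustering settings.
#' @inheritParams differential_by_timepoint
#' @return List of class `screen_result`: per-timepoint `diff_calls`,
#'   `categories`, `profiles`, `clusters` (per category), `consistent_hyper`,
#'   `stage2` sets, and the final `candidates`.
#' @export
screen_two_stage <- function(mat, exposed_dose = NULL, fc_hi = 2, fc_lo = 0.5,
                             alpha = 0.01, welch = FALSE,
                             stage2_tps = NULL, n_clusters = 2,
                             fuzzifier = 2, seed = 1L) {
  calls <- differential_by_timepoint(mat, exposed_dose = exposed_dose,
                                     fc_hi = fc_hi, fc_lo = fc_lo,
                                     alpha = alpha, welch = welch)
  tps <- as.numeric(names(calls))
  genes <- calls[[1]]$gene_id
  status <- sapply(calls, function(d) d$status)
  lfc <- sapply(calls, function(d) d$log2_fc)
  rownames(status) <- rownames(lfc) <- genes
  categories <- assign_category(status)

  if (is.null(stage2_tps)) {
    stage2_tps <- intersect(c(1, 14), tps)
    if (length(stage2_tps) < 2) stage2_tps <- range(tps)
  }
  if (!all(stage2_tps %in% tps)) stop("stage2_tps not in the design")

  clusters <- list()
  consistent <- list(Hyper = character(0), Hypo = character(0))
  for (cat_name in c("Hyper", "Hypo")) {
    ids <- names(categories)[categories == cat_name]
    if (length(ids) >= n_clusters) {
      prof <- lfc[ids, , drop = FALSE]
      cl <- cluster_time_profiles(prof, n_clusters = n_clusters,
                                  fuzzifier = fuzzifier, seed = seed)
      clusters[[cat_name]] <- cl
      consistent[[cat_name]] <- select_consistent(prof, cl, cat_name)
    } else if (length(ids) > 0) {
      # too few members to cluster: keep those consistent on their own profile
      prof <- lfc[ids, , drop = FALSE]
      ok <- if (cat_name == "Hyper") apply(prof, 1, min) > 0
            else apply(prof, 1, max) < 0
      consistent[[cat_name]] <- ids[ok]
    }
  }

  stage2 <- lapply(stage2_tps, function(tp) {
    d <- calls[[as.character(tp)]]
    d$gene_id[d$status == "hyper"]
  })
  names(stage2) <- sprintf("hyper_day%g", stage2_tps)

  sets <- c(list(consistent_hyper = consistent$Hyper), stage2)
  candidates <- intersect_candidates(sets)

  structure(list(diff_calls = calls, categories = categories,
                 profiles = lfc, status = status, clusters = clusters,
                 consistent_hyper = consistent$Hyper,
                 consistent_hypo = consistent$Hypo,
                 stage2 = stage2, candidates = candidates),
            class = "screen_result")
}
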