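#' Cross-mediator SSD similarity (dissimilarity) matrix
#'
#' For every ordered pair (i, j), registers mediator i to mediator j,
#' histogram-matches the warped image to mediator j, and records the SSD on
#' mediator j's grid. The matrix is then symmetrized by averaging the (i, j)
#' and (j, i) entries (the two directed registrations differ in general), and
#' the diagonal is 0 by definition. A pairwise registration failure is
#' recorded and the entry imputed as the row maximum.
#'
#' @param library a `medbridge_library` with at least 2 mediators.
#' @param cfg a [registration_config()].
#' @param match_levels histogram-matching quantile levels.
#' @return A list of class `medbridge_simmatrix`: `ids`, `values` (N x N,
#'   symmetric, zero diagonal), `symmetrized`, `failed` (data.frame of
#'   imputed directed pairs, possibly empty).
#' @export
build_similarity_matrix <- function(library, cfg = registration_config(),
                                    match_levels = 256L) {
  stopifnot(inherits(library, "medbridge_library"))
  n <- length(library$entries)
  if (n < 2L) stop("need at least 2 mediators")
  ids <- library_ids(library)
  raw <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(raw) <- 0
  failed <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      mi_ <- library$entries[[i]]
      mj <- library$entries[[j]]
      raw[i, j] <- tryCatch({
        reg <- register_affine(mi_$volume, mj$volume, cfg,
                               from_space = mi_$id, to_space = mj$id)
        warped <- resample(mi_$volume, mj$volume, reg$transform)
        warped_matched <- histogram_match(warped, mj$volume, match_levels)
        ssd(warped_matched, mj$volume)
      }, error = function(e) {
        failed[[length(failed) + 1L]] <<- data.frame(
          from = mi_$id, to = mj$id, message = conditionMessage(e),
          stringsAsFactors = FALSE)
        NA_real_
      })
    }
  }
  for (i in seq_len(n)) {
    bad <- is.na(raw[i, ])
    if (any(bad)) raw[i, bad] <- max(raw[i, !bad], na.rm = TRUE)
  }
  values <- (raw + base::t(raw)) / 2
  diag(values) <- 0
  structure(list(ids = ids, values = values, symmetrized = TRUE,
                 failed = if (length(failed)) do.call(rbind, failed)
                          else data.frame(from = character(), to = character(),
                                          message = character())),
            class = "medbridge_simmatrix")
}

#' Cluster a mediator library into k groups
#'
#' Agglomerative hierarchical clustering with complete linkage on the
#' symmetrized SSD dissimilarity matrix, dendrogram cut at exactly `k`
#' clusters. Each cluster is represented by its medoid — the member with the
#' smallest summed dissimilarity to its co-members (a singleton represents
#' itself); ties break toward the lexicographically lowest id.
#'
#' @param sim a `medbridge_simmatrix` (or symmetric matrix with id dimnames).
#' @param k number of clusters, `1 <= k <= N`.
#' @return A list of class `medbridge_clusters`: `k`, `labels` (named integer
#'   vector, id -> cluster), `representatives` (character vector of length
#'   `k`, cluster -> id), and the underlying `hclust` tree.
#' @export
cluster_library <- function(sim, k) {
  if (inherits(sim, "medbridge_simmatrix")) {
    values <- sim$values; ids <- sim$ids
  } else {
    values <- as.matrix(sim); ids <- rownames(values)
  }
  n <- nrow(values)
  if (k < 1L || k > n) stop("k must be between 1 and ", n)
  if (max(abs(values - base::t(values))) > 1e-9)
    stop("similarity matrix is not symmetric")
  dimnames(values) <- list(ids, ids)
  tree <- hclust(as.dist(values), method = "complete")
  labels <- cutree(tree, k = k)
  reps <- vapply(seq_len(k), function(g) {
    members <- ids[labels == g]
    if (length(members) == 1L) return(members)
    sums <- vapply(members, function(m)
      sum(values[m, setdiff(members, m)]), numeric(1))
    members <- members[order(sums, members)]
    members[1L]
  }, character(1))
  structure(list(k = as.integer(k), labels = labels,
                 representatives = reps, tree = tree),
            class = "medbridge_clusters")
}

#' Shrink a library to its cluster representatives
#'
#' Keeps only the representative (medoid) mediator of each cluster,
#' preserving the original library order; the template is unchanged. This is
#' the computational shortcut of the framework: mediators that register to
#' each other with low SSD carry redundant geometric information, so one per
#' cluster suffices.
#'
#' @param library the full `medbridge_library`.
#' @param assignment a `medbridge_clusters` from [cluster_library()].
#' @return A smaller `medbridge_library`.
#' @export
shrink_library <- function(library, assignment) {
  stopifnot(inherits(library, "medbridge_library"),
            inherits(assignment, "medbridge_clusters"))
  ids <- library_ids(library)
  reps <- assignment$representatives
  unknown <- setdiff(reps, ids)
  if (length(unknown))
    stop("representatives not in library: ", paste(unknown, collapse = ", "))
  keep <- ids %in% reps
  mediator_library(library$template, library$template_mask,
                   library$entries[keep], space_label = library$space_label)
}

#' Write a similarity matrix as CSV (id header row and column)
#' @param sim a `medbridge_simmatrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  stopifnot(inherits(sim, "medbridge_simmatrix"))
  df <- as.data.frame(sim$values)
  df <- cbind(id = sim$ids, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
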