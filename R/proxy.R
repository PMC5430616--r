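#' Rank samples by extremity on a principal component
#'
#' Orders candidate reference samples by their signed coordinate on one
#' principal component, most extreme first — the samples at a pole of an
#' ancestry axis carry the least admixture from the other ancestries and make
#' the best supervising proxies.  Stable sort; ties break by sample id.
#'
#' @param scores matrix of projected coordinates (samples x components) with
#'   sample ids as row names
#' @param pc_index which component to rank on
#' @param direction `"min"` (most negative first) or `"max"`
#' @return character vector of sample ids, most extreme first
#' @export
rank_by_pc <- function(scores, pc_index, direction = c("min", "max")) {
  direction <- match.arg(direction)
  x <- scores[, pc_index]
  ids <- rownames(scores)
  o <- order(if (direction == "min") x else -x, ids)
  ids[o]
}

#' Select equal-size proxy panels from per-ancestry rankings
#'
#' Builds one panel of exactly `n_proxy` samples per ancestry from ordered
#' candidate rankings.  A sample appearing in several rankings is claimed by
#' the ancestry where its rank is more extreme (smaller); ties go to the
#' earlier ancestry in the list order.
#'
#' @param rankings named list of ordered sample-id vectors (most extreme
#'   first), one per ancestry
#' @param n_proxy panel size, equal across ancestries
#' @return named list of `proxy_panel` objects: `ancestry`, `ids` (ordered),
#'   `n_selected`
#' @export
select_proxies <- function(rankings, n_proxy) {
  stopifnot(is.list(rankings), length(names(rankings)) == length(rankings))
  # resolve overlaps: more extreme rank wins
  claim <- new.env(parent = emptyenv())
  for (anc in names(rankings)) {
    r <- rankings[[anc]]
    for (i in seq_along(r)) {
      cur <- claim[[r[i]]]
      if (is.null(cur) || i < cur$rank)
        claim[[r[i]]] <- list(anc = anc, rank = i)
    }
  }
  out <- lapply(names(rankings), function(anc) {
    r <- rankings[[anc]]
    mine <- r[vapply(r, function(id) claim[[id]]$anc == anc, logical(1))]
    if (length(mine) < n_proxy)
      stop("ancestry '", anc, "' has only ", length(mine),
           " candidates after overlap resolution (need ", n_proxy, ")")
    structure(list(ancestry = anc, ids = mine[seq_len(n_proxy)],
                   n_selected = n_proxy),
              class = "proxy_panel")
  })
  names(out) <- names(rankings)
  out
}

#' Panel assignment vector from proxy panels
#'
#' Convenience: flattens a list of panels into the named `sample -> ancestry`
#' vector taken by [fit_supervised()].
#'
#' @param panels list of `proxy_panel` objects
#' @return named character vector
#' @export
proxy_assignment <- function(panels) {
  ids <- unlist(lapply(panels, `[[`, "ids"))
  anc <- rep(vapply(panels, `[[`, "", "ancestry"),
             vapply(panels, function(p) length(p$ids), integer(1)))
  setNames(anc, ids)
}

#' Bootstrap standard error of mean ancestry vs proxy panel size
#'
#' For each candidate panel size `n`, builds equal-size panels from the
#' rankings, then bootstraps loci (resampling SNPs with replacement,
#' panels fixed), refits the supervised model on each replicate, and records
#' the cohort-mean ancestry vector.  The SE at a given `n` is the
#' per-component standard deviation across replicates, summarized by its
#' mean over components.  The panel size minimizing the SE balances the
#' variance reduction from more supervising samples against contamination of
#' less-extreme candidates by admixture.
#'
#' @param gm a `geno_matrix` containing cohort and candidate proxy samples
#' @param rankings named list of per-ancestry ordered candidate ids
#' @param n_candidates integer vector of panel sizes to evaluate
#' @param B bootstrap replicates per size (>= 50)
#' @param seed integer seed
#' @param cohort_samples ids over which the mean ancestry is taken (default:
#'   all samples not in any panel at the current size)
#' @param tol EM tolerance inside replicates (default 1e-5; reduced for
#'   speed, the final fit should use the full tolerance)
#' @param max_iter EM iteration limit per replicate fit
#' @return list of class `proxy_size_curve`: `n_values`, `se` (mean over
#'   components), `se_components` (matrix), `argmin_n`, `B`, `seed`
#' @export
proxy_size_curve <- function(gm, rankings, n_candidates, B = 100, seed = 1,
                             cohort_samples = NULL, tol = 1e-5,
                             max_iter = 500) {
  stopifnot(B >= 50)
  K <- length(rankings)
  se_comp <- matrix(NA_real_, length(n_candidates), K,
                    dimnames = list(NULL, names(rankings)))
  for (ni in seq_along(n_candidates)) {
    n <- n_candidates[ni]
    panels <- select_proxies(rankings, n)
    assign <- proxy_assignment(panels)
    cohort <- cohort_samples %||% setdiff(sample_ids(gm), names(assign))
    sub <- subset_geno(gm, samples = c(cohort, names(assign)))
    means <- matrix(NA_real_, B, K)
    dropped <- 0L
    for (b in seq_len(B)) {
      set.seed(seed + 7919L * ni + b)
      loci <- sample.int(n_snps(sub), n_snps(sub), replace = TRUE)
      # resampled loci repeat, so rebuild the matrix with uniquified ids
      db <- sub$dosage[, loci, drop = FALSE]
      mapb <- sub$snps[loci, , drop = FALSE]
      mapb$id <- make.unique(mapb$id)
      colnames(db) <- mapb$id
      gb <- geno_matrix(db, mapb)
      fit <- tryCatch(
        fit_supervised(gb, proxy_assignment = assign,
                       seed = seed + b, n_restarts = 1, tol = tol,
                       max_iter = max_iter),
        warning = function(w) NULL)
      if (is.null(fit)) { dropped <- dropped + 1L; next }
      means[b, ] <- colMeans(fit$Q[cohort, , drop = FALSE])
    }
    if (dropped > 0.1 * B)
      stop(">10% of bootstrap replicates failed to converge at n=", n)
    se_comp[ni, ] <- apply(means, 2, sd, na.rm = TRUE)
  }
  se <- rowMeans(se_comp)
  structure(list(n_values = n_candidates, se = se, se_components = se_comp,
                 argmin_n = n_candidates[which.min(se)], B = B, seed = seed),
            class = "proxy_size_curve")
}

#' @export
print.proxy_size_curve <- function(x, ...) {
  print(data.frame(n = x$n_values, se_mean = x$se))
  cat("argmin n:", x$argmin_n, "\n")
  invisible(x)
}

#' Write proxy panels as TSV
#'
#' @param panels list of `proxy_panel` objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_panels <- function(panels, path) {
  tab <- do.call(rbind, lapply(panels, function(p)
    data.frame(sample_id = p$ids, ancestry = p$ancestry,
               rank = seq_along(p$ids), stringsAsFactors = FALSE)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign ancestry groups to principal-component poles
#'
#' Given projected scores of labeled candidate reference samples, finds for
#' each group the (component, direction) pole where its centroid is most
#' extreme (in standard-deviation units), greedily ensuring distinct poles.
#' This derives the pole -> ancestry mapping from labeled references; the
#' labels themselves must be supplied by the caller.
#'
#' @param scores projected coordinates of candidate samples (samples x
#'   components, sample ids as row names)
#' @param groups named character vector: sample id -> group label
#' @param pcs which components to consider (default `1:2`)
#' @return list of poles: each `list(ancestry, pc_index, direction)`
#' @export
assign_poles <- function(scores, groups, pcs = 1:2) {
  groups <- groups[rownames(scores)]
  labs <- unique(groups[!is.na(groups)])
  z <- scale(scores[, pcs, drop = FALSE])
  cand <- expand.grid(lab = labs, pc = pcs, dir = c("min", "max"),
                      stringsAsFactors = FALSE)
  cand$score <- mapply(function(lab, pc, dir) {
    ctr <- mean(z[which(groups == lab), match(pc, pcs)])
    if (dir == "max") ctr else -ctr
  }, cand$lab, cand$pc, cand$dir)
  cand <- cand[order(-cand$score), ]
  poles <- list()
  used_pole <- character(0)
  for (i in seq_len(nrow(cand))) {
    lab <- cand$lab[i]
    key <- paste(cand$pc[i], cand$dir[i])
    if (lab %in% names(poles) || key %in% used_pole) next
    poles[[lab]] <- list(ancestry = lab, pc_index = cand$pc[i],
                         direction = cand$dir[i])
    used_pole <- c(used_pole, key)
    if (length(poles) == length(labs)) break
  }
  if (length(poles) < length(labs))
    stop("could not assign a distinct pole to every group; increase pcs")
  poles[labs]
}
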