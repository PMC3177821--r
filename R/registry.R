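# Beta-sheet registry statistics: the pairing pattern of a two-stranded
# inter-chain beta-sheet, indexed by i - j (parallel) or i + j
# (antiparallel) of bridged residue numbers in Abeta numbering.

#' Classify the beta-sheet registry of one frame
#'
#' Finds the DSSP bridges between the two chains and reduces them to a
#' single registry label: the orientation of the pairing (parallel if
#' the partner residue number increases with the reference residue
#' number, antiparallel if it decreases) and the modal registry index —
#' `i - j` over parallel bridge pairs or `i + j` over antiparallel ones.
#' Ties are broken toward the index supported by more hydrogen-bond
#' energy. Frames whose bridges mix both orientations are flagged and
#' excluded from histograms; frames without inter-chain bridges return
#' orientation `"none"`.
#'
#' @param ens a [dimer_ensemble()] with exactly two chains.
#' @param frame frame index.
#' @param min_bridges minimum number of inter-chain bridge pairs
#'   required before a frame is binned (default 1).
#' @param chains length-2 character: reference chain first; the parallel
#'   index is the label-ordered difference `i(chains[1]) - j(chains[2])`.
#' @return list with `orientation` (`"parallel"`, `"antiparallel"`,
#'   `"none"` or `"conflict"`), `index` (NA unless classified) and
#'   `pairs` (the inter-chain bridge pairs as a data.frame).
#' @export
classify_frame_registry <- function(ens, frame = 1L, min_bridges = 1L,
                                    chains = NULL) {
  stopifnot(inherits(ens, "dimer_ensemble"))
  rt <- .residue_table(ens$atoms)
  if (is.null(chains)) chains <- sort(unique(rt$chain))
  if (length(chains) != 2) stop("registry classification needs two chains")
  g <- hbond_graph(ens, frame)
  br <- .frame_bridges(rt, g)
  inter <- br[rt$chain[br$i] != rt$chain[br$j], , drop = FALSE]
  if (nrow(inter)) {
    # orient pairs as (reference chain, partner chain)
    flip <- rt$chain[inter$i] != chains[1]
    ii <- ifelse(flip, inter$j, inter$i)
    jj <- ifelse(flip, inter$i, inter$j)
    pairs <- data.frame(i = rt$resno[ii], j = rt$resno[jj],
                        type = inter$type, stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(i = integer(), j = integer(), type = character(),
                        stringsAsFactors = FALSE)
  }
  if (nrow(pairs) < min_bridges)
    return(list(orientation = "none", index = NA_integer_, pairs = pairs))
  tys <- unique(pairs$type)
  if (length(tys) > 1)
    return(list(orientation = "conflict", index = NA_integer_,
                pairs = pairs))
  idx <- if (tys == "parallel") pairs$i - pairs$j else pairs$i + pairs$j
  tab <- table(idx)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) > 1) {
    # tie-break: total inter-chain H-bond energy supporting each index
    supp <- vapply(top, function(k) {
      keep <- pairs[idx == k, , drop = FALSE]
      gi <- g[g$donor_chain != g$acc_chain, , drop = FALSE]
      if (!nrow(gi)) return(0)
      ksum <- if (tys == "parallel") gi$donor_res - gi$acc_res
              else gi$donor_res + gi$acc_res
      sum(gi$energy[abs(ksum - k) <= 1])
    }, 0)
    top <- top[which.min(supp)]
  }
  list(orientation = tys, index = top[1], pairs = pairs)
}

#' Registry population histograms over an ensemble
#'
#' Classifies every frame with [classify_frame_registry()] and reports,
#' per orientation, the population of each registry index (normalized by
#' the total frame count, so populations across both orientations plus
#' the no-bridge and conflict fractions sum to 1). Standard errors come
#' from block averaging of the per-frame indicator series.
#'
#' @param ens a [dimer_ensemble()].
#' @param min_bridges,chains passed to [classify_frame_registry()].
#' @param n_blocks blocks for the error estimate.
#' @return object of class `"registry_histogram"`: list with
#'   `parallel` and `antiparallel` data.frames (index, population,
#'   stderr), `no_bridge`, `conflict` fractions, `per_frame`
#'   (orientation and index per frame) and `n_frames`.
#' @export
registry_histogram <- function(ens, min_bridges = 1L, chains = NULL,
                               n_blocks = 5L) {
  stopifnot(inherits(ens, "dimer_ensemble"))
  nf <- n_frames(ens)
  ori <- character(nf); idx <- rep(NA_integer_, nf)
  for (f in seq_len(nf)) {
    cl <- classify_frame_registry(ens, f, min_bridges, chains)
    ori[f] <- cl$orientation; idx[f] <- cl$index
  }
  one <- function(which) {
    sel <- ori == which
    vals <- sort(unique(idx[sel]))
    if (!length(vals))
      return(data.frame(index = integer(), population = numeric(),
                        stderr = numeric()))
    pop <- vapply(vals, function(k) mean(sel & idx == k & !is.na(idx)), 0)
    se <- vapply(vals, function(k) {
      ind <- as.numeric(sel & !is.na(idx) & idx == k)
      if (nf >= n_blocks) block_average_error(ind, n_blocks) else NA_real_
    }, 0)
    data.frame(index = vals, population = pop, stderr = se)
  }
  structure(list(parallel = one("parallel"),
                 antiparallel = one("antiparallel"),
                 no_bridge = mean(ori == "none"),
                 conflict = mean(ori == "conflict"),
                 per_frame = data.frame(orientation = ori, index = idx),
                 n_frames = nf),
            class = "registry_histogram")
}

#' @export
print.registry_histogram <- function(x, ...) {
  cat(sprintf("registry_histogram over %d frames (no-bridge %.2f, conflict %.2f)\n",
              x$n_frames, x$no_bridge, x$conflict))
  if (nrow(x$parallel)) { cat("parallel (i-j):\n"); print(x$parallel) }
  if (nrow(x$antiparallel)) { cat("antiparallel (i+j):\n"); print(x$antiparallel) }
  invisible(x)
}

#' Write registry histograms as TSV + JSON summary
#'
#' @param rh a [registry_histogram()].
#' @param stem output path stem; writes `<stem>.tsv` and
#'   `<stem>_top.json` (top-`k` patterns).
#' @param k how many top patterns to summarize.
#' @return `stem`, invisibly.
#' @export
write_registry <- function(rh, stem, k = 5L) {
  stopifnot(inherits(rh, "registry_histogram"))
  tab <- rbind(
    if (nrow(rh$parallel)) cbind(orientation = "parallel", rh$parallel),
    if (nrow(rh$antiparallel)) cbind(orientation = "antiparallel",
                                     rh$antiparallel))
  utils::write.table(tab, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ord <- order(-tab$population)
  top <- utils::head(tab[ord, , drop = FALSE], k)
  jsonlite::write_json(
    list(n_frames = rh$n_frames, no_bridge = rh$no_bridge,
         conflict = rh$conflict,
         top_patterns = top),
    paste0(stem, "_top.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
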