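#' @importFrom stats median sd
NULL

#' Locate the intron containing each intronic tag
#'
#' For every tag classified as intronic, finds its containing intron and
#' computes the intron length and the distances from the tag to both splice
#' sites. Distances use the exclusive-gap convention — the number of
#' intronic nucleotides strictly between the splice junction and the tag's
#' proximal end, so a tag abutting the junction has distance 0 and
#' \code{dist_upstream + tag_length + dist_downstream == intron_length}
#' always holds. Upstream/downstream are transcription-direction terms: the
#' upstream splice site of an intron is its donor.
#'
#' @param alignments GRanges of unique placements (with \code{tag_id}), or
#'   the mapping \code{DataFrame}.
#' @param models a \linkS4class{GeneModels}.
#' @param assignments optional data.frame from
#'   \code{\link{assignGeneContext}}; computed when missing. Only tags with
#'   category \code{intron} are used.
#' @return data.frame with one row per intronic tag: \code{tag_id},
#'   \code{gene_id}, \code{chrom}, \code{intron_start}, \code{intron_end},
#'   \code{intron_length}, \code{tag_length}, \code{dist_upstream},
#'   \code{dist_downstream}.
#' @export
locateContainingIntron <- function(alignments, models, assignments = NULL) {
    if (!is(alignments, "GRanges"))
        alignments <- alignmentsAsGRanges(alignments)
    if (is.null(assignments))
        assignments <- assignGeneContext(alignments, models)
    keep <- assignments$category == "intron"
    idx <- which(keep)
    introns <- intronBlocks(models)
    rows <- vector("list", length(idx))
    for (r in seq_along(idx)) {
        i <- idx[r]
        gid <- assignments$gene_id[i]
        tag <- alignments[i]
        intr <- introns[[gid]]
        hit <- which(start(intr) <= start(tag) & end(intr) >= end(tag))
        if (length(hit) == 0L) {
            cover <- which(start(intr) <= end(tag) & end(intr) >= start(tag))
            if (length(cover) > 1L)
                stop("tag ", assignments$tag_id[i],
                     " spans multiple introns")
            ## majority-intronic straddler: clip to its (single) intron
            hit <- cover
            tag <- GenomicRanges::restrict(tag, start = start(intr)[hit],
                                           end = end(intr)[hit])
        }
        intr1 <- intr[hit]
        left_gap <- start(tag) - start(intr1)
        right_gap <- end(intr1) - end(tag)
        minus <- as.character(strand(intr1)) == "-"
        rows[[r]] <- data.frame(
            tag_id = assignments$tag_id[i], gene_id = gid,
            chrom = as.character(seqnames(intr1)),
            intron_start = start(intr1), intron_end = end(intr1),
            intron_length = width(intr1), tag_length = width(tag),
            dist_upstream = if (minus) right_gap else left_gap,
            dist_downstream = if (minus) left_gap else right_gap,
            stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(tag_id = character(), gene_id = character(),
                    chrom = character(), intron_start = integer(),
                    intron_end = integer(), intron_length = integer(),
                    tag_length = integer(), dist_upstream = integer(),
                    dist_downstream = integer(), stringsAsFactors = FALSE)
}

#' Summary statistics of intron geometry
#'
#' Mean, standard error of the mean (sample sd / sqrt(n)), median, min,
#' max and n for intron length and both splice-site distances — the shape
#' of the classic tag-containing-intron summary table. With a single
#' context the SEM is reported as 0 and flagged.
#'
#' @param contexts data.frame from \code{\link{locateContainingIntron}} (or
#'   any table with \code{intron_length}, \code{dist_upstream},
#'   \code{dist_downstream}).
#' @return data.frame with one row per metric and columns \code{metric},
#'   \code{n}, \code{mean}, \code{sem}, \code{median}, \code{min},
#'   \code{max}, \code{sem_defined}.
#' @examples
#' summarizeGeometry(data.frame(intron_length = c(370, 247578),
#'                              dist_upstream = c(100, 200),
#'                              dist_downstream = c(240, 247348)))
#' @export
summarizeGeometry <- function(contexts) {
    if (nrow(contexts) == 0L) stop("no intron contexts to summarize")
    metrics <- c("intron_length", "dist_upstream", "dist_downstream")
    do.call(rbind, lapply(metrics, function(m) {
        x <- contexts[[m]]
        n <- length(x)
        data.frame(metric = m, n = n, mean = mean(x),
                   sem = if (n > 1) sd(x) / sqrt(n) else 0,
                   median = median(x), min = min(x), max = max(x),
                   sem_defined = n > 1, stringsAsFactors = FALSE)
    }))
}

#' Fractions of tags proximal to splice sites
#'
#' Fraction of intronic tags lying within \code{threshold} nt of the
#' upstream (donor) splice site, the downstream (acceptor) splice site, and
#' of at least one of them (the minimum of the two distances).
#'
#' @param contexts data.frame of intron contexts.
#' @param threshold distance threshold in nt (default 500).
#' @return named numeric vector: \code{within_upstream},
#'   \code{within_downstream}, \code{within_either}.
#' @export
proximityFractions <- function(contexts, threshold = 500) {
    stopifnot(threshold > 0)
    n <- nrow(contexts)
    if (n == 0L)
        return(c(within_upstream = NA_real_, within_downstream = NA_real_,
                 within_either = NA_real_))
    up <- contexts$dist_upstream <= threshold
    dn <- contexts$dist_downstream <= threshold
    c(within_upstream = sum(up) / n,
      within_downstream = sum(dn) / n,
      within_either = sum(pmin(contexts$dist_upstream,
                               contexts$dist_downstream) <= threshold) / n)
}

#' Bin intron lengths
#'
#' Half-open bins \code{(-Inf, b1), [b1, b2), ..., [bk, Inf)} over the
#' containing-intron lengths; fractions sum to 1.
#'
#' @param contexts data.frame of intron contexts, or a numeric vector of
#'   intron lengths.
#' @param bounds strictly increasing bin bounds (nt), default
#'   \code{c(10000, 100000)}.
#' @return named numeric vector of per-bin fractions.
#' @examples
#' lengthBins(c(5000, 50000, 150000))
#' @export
lengthBins <- function(contexts, bounds = c(10000, 100000)) {
    stopifnot(!is.unsorted(bounds, strictly = TRUE))
    len <- if (is.numeric(contexts)) contexts else contexts$intron_length
    brk <- c(-Inf, bounds, Inf)
    labs <- c(paste0("<", bounds[1]),
              if (length(bounds) > 1)
                  paste0(bounds[-length(bounds)], "-", bounds[-1]),
              paste0(">=", bounds[length(bounds)]))
    cnt <- table(cut(len, breaks = brk, right = FALSE, labels = labs))
    setNames(as.numeric(cnt) / length(len), labs)
}

#' Side-by-side geometry summaries for several datasets
#'
#' Stacks \code{\link{summarizeGeometry}} blocks for any number of context
#' tables (e.g. tag sets from different species or proteins) into one
#' comparison table.
#'
#' @param ... named context data.frames, or a single named list of them.
#' @return data.frame with a leading \code{dataset} column.
#' @export
runComparison <- function(...) {
    sets <- list(...)
    if (length(sets) == 1L && is.list(sets[[1]]) &&
        !is.data.frame(sets[[1]]))
        sets <- sets[[1]]
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        names(sets) <- paste0("dataset", seq_along(sets))
    do.call(rbind, lapply(names(sets), function(nm) {
        cbind(dataset = nm, summarizeGeometry(sets[[nm]]))
    }))
}
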