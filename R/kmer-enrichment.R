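#' @importFrom Biostrings oligonucleotideFrequency vcountPattern
NULL

tagSeqsAsRNA <- function(tags) {
    if (is(tags, "ClipTagSet")) tagSequences(tags, "RNA")
    else if (is(tags, "RNAStringSet")) tags
    else if (is(tags, "DNAStringSet"))
        RNAStringSet(dnaToRna(as.character(tags)))
    else RNAStringSet(dnaToRna(as.character(tags)))
}

#' Count k-mer incidence over a tag set
#'
#' Counts every overlapping window (step 1) of width \code{k} across the
#' distinct tags, summed over tags, in the RNA alphabet. Windows containing
#' ambiguous bases are excluded from both the counts and the window total.
#' The uniform expectation — the incidence each k-mer would have if all
#' 4^k words were equally represented — is \code{total_windows / 4^k}; a
#' composition-adjusted expectation (product of observed mononucleotide
#' frequencies) is available as an option.
#'
#' @param tags a \linkS4class{ClipTagSet}, \code{DNAStringSet},
#'   \code{RNAStringSet} or character vector (counted as distinct
#'   sequences, unweighted by occurrence count).
#' @param k word size, 1 to 6.
#' @param expectation "uniform" (default) or "composition".
#' @return list with \code{k}, \code{counts} (named integer over all 4^k
#'   RNA words), \code{total_windows} and \code{expected} (per-k-mer
#'   expected incidence; scalar for uniform).
#' @examples
#' countKmers("UGUG", 2)$counts[c("UG", "GU")]
#' @export
countKmers <- function(tags, k, expectation = c("uniform", "composition")) {
    expectation <- match.arg(expectation)
    if (!is.numeric(k) || length(k) != 1L || k < 1 || k > 6)
        stop("k must be a single integer in 1..6")
    k <- as.integer(k)
    seqs <- tagSeqsAsRNA(tags)
    counts <- colSums(oligonucleotideFrequency(seqs, width = k, step = 1))
    counts <- counts[order(names(counts))]
    total <- sum(counts)
    expected <- if (expectation == "uniform") {
        rep(total / 4^k, length(counts)) |> setNames(names(counts))
    } else {
        mono <- colSums(oligonucleotideFrequency(seqs, width = 1))
        p <- mono / sum(mono)
        vapply(names(counts), function(w) {
            total * prod(p[strsplit(w, "")[[1]]])
        }, numeric(1))
    }
    list(k = k, counts = counts, total_windows = total, expected = expected)
}

#' Rank the most frequent k-mers
#'
#' Orders k-mers by descending count; ties are broken lexicographically.
#'
#' @param table result of \code{\link{countKmers}}.
#' @param top_n number of k-mers to return (the full ranking if fewer
#'   distinct words are observed).
#' @param drop_zero drop k-mers never observed (default TRUE).
#' @return data.frame with columns \code{kmer}, \code{count},
#'   \code{expected}.
#' @export
rankKmers <- function(table, top_n = 20L, drop_zero = TRUE) {
    stopifnot(top_n >= 1)
    cnt <- table$counts
    exp <- table$expected
    if (drop_zero) {
        keep <- cnt > 0
        cnt <- cnt[keep]; exp <- exp[keep]
    }
    ord <- order(-cnt, names(cnt))
    n <- min(top_n, length(cnt))
    idx <- ord[seq_len(n)]
    data.frame(kmer = names(cnt)[idx], count = unname(cnt[idx]),
               expected = unname(exp[idx]), stringsAsFactors = FALSE)
}

#' Per-tag motif occurrence distribution
#'
#' Counts overlapping occurrences of a motif in each tag and histograms the
#' per-tag counts — the representation used to show that motif enrichment
#' is spread across a tag set rather than driven by a few motif-dense tags.
#'
#' @param tags tag set (as in \code{\link{countKmers}}).
#' @param motif RNA-alphabet motif (e.g. "UG").
#' @return list with \code{motif}, \code{per_tag} (named integer) and
#'   \code{histogram} (table of occurrences-per-tag -> number of tags).
#' @examples
#' motifCountDistribution(c("UGUG", "ACCA"), "UG")$histogram
#' @export
motifCountDistribution <- function(tags, motif) {
    seqs <- tagSeqsAsRNA(tags)
    motif_rna <- dnaToRna(motif)
    per_tag <- vcountPattern(motif_rna, seqs)
    names(per_tag) <- names(seqs)
    list(motif = motif_rna, per_tag = per_tag,
         histogram = table(per_tag))
}

#' Welch one-tailed comparison of per-tag motif counts between groups
#'
#' Compares mean per-tag motif occurrences between two tag groups with a
#' t-test assuming unequal variances (Welch), one-tailed in the declared
#' direction. This is the comparison behind contrasts such as "UG counts in
#' UTR tags versus coding-exon tags".
#'
#' @param group_a,group_b tag sets or numeric vectors of per-tag motif
#'   counts.
#' @param motif motif to count when tag sets are given.
#' @param direction "greater" tests mean(a) > mean(b) (default), "less" the
#'   reverse.
#' @return list with \code{t}, \code{df}, \code{p_value},
#'   \code{mean_a}, \code{mean_b}, \code{direction}.
#' @examples
#' compareGroupMotifCounts(c(2, 4, 6), c(1, 2, 3))
#' @export
compareGroupMotifCounts <- function(group_a, group_b, motif = "UG",
                                    direction = c("greater", "less")) {
    direction <- match.arg(direction)
    a <- if (is.numeric(group_a)) group_a
         else motifCountDistribution(group_a, motif)$per_tag
    b <- if (is.numeric(group_b)) group_b
         else motifCountDistribution(group_b, motif)$per_tag
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 observations")
    if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
        ## degenerate but symmetric: no evidence either way
        return(list(t = 0, df = length(a) + length(b) - 2,
                    p_value = 0.5, mean_a = mean(a), mean_b = mean(b),
                    direction = direction))
    }
    if (stats::var(a) == 0 && stats::var(b) == 0)
        stop("both groups have zero variance")
    ht <- stats::t.test(a, b, alternative = direction, var.equal = FALSE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b),
         direction = direction)
}

#' Bar chart of k-mer incidence with the uniform-expectation line
#'
#' @param table result of \code{\link{countKmers}}.
#' @param top_n label/limit to this many k-mers for k > 2.
#' @param main plot title.
#' @return invisibly, the plotted counts.
#' @export
plotKmerIncidence <- function(table, top_n = 40L, main = NULL) {
    cnt <- sort(table$counts, decreasing = TRUE)
    if (table$k > 2) cnt <- cnt[seq_len(min(top_n, length(cnt)))]
    exp_line <- table$total_windows / 4^table$k
    bp <- graphics::barplot(cnt, las = 2,
                            cex.names = if (table$k <= 2) 0.8 else 0.5,
                            ylab = "incidence",
                            main = main %||% paste0(table$k, "-mer incidence"))
    graphics::abline(h = exp_line, col = "darkgreen", lty = 3)
    invisible(cnt)
}

#' Histogram of per-tag motif counts for two motifs side by side
#'
#' @param tags tag set.
#' @param motifs character vector of motifs (default UG and its
#'   composition-matched control CA).
#' @param main plot title.
#' @return invisibly, the matrix of histogram counts.
#' @export
plotMotifHistograms <- function(tags, motifs = c("UG", "CA"), main = NULL) {
    dists <- lapply(motifs, function(m)
        motifCountDistribution(tags, m)$per_tag)
    maxc <- max(unlist(dists))
    h <- vapply(dists, function(d) tabulate(d + 1L, nbins = maxc + 1L),
                integer(maxc + 1L))
    colnames(h) <- motifs
    rownames(h) <- 0:maxc
    graphics::barplot(t(h), beside = TRUE, legend.text = motifs,
                      xlab = "motif occurrences per tag",
                      ylab = "number of tags",
                      main = main %||% "per-tag motif counts")
    invisible(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
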