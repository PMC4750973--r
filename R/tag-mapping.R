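#' @importFrom Biostrings vcountPattern matchPattern
NULL

#' Flag contaminant tags against a reference
#'
#' A tag is a contaminant when it occurs as an exact substring of the
#' contaminant reference (bacterial rRNA and the like) on either strand.
#' Screening precedes genome mapping: a tag matching both the reference and
#' the genome is reported as contaminant.
#'
#' @param tags a \linkS4class{ClipTagSet}, \code{DNAStringSet} or character
#'   vector of tag sequences.
#' @param reference contaminant reference, \code{DNAStringSet} or path to a
#'   FASTA file.
#' @return named logical vector, TRUE for contaminants.
#' @export
flagContaminants <- function(tags, reference) {
    seqs <- tagSeqsAsDNA(tags)
    if (is.character(reference) && length(reference) == 1L &&
        file.exists(reference))
        reference <- readDNAStringSet(reference)
    if (length(reference) == 0L) stop("contaminant reference is empty")
    ref <- c(reference, reverseComplement(reference))
    vapply(seq_along(seqs), function(i) {
        any(vcountPattern(seqs[[i]], ref) > 0L)
    }, logical(1), USE.NAMES = FALSE) |> setNames(names(seqs))
}

tagSeqsAsDNA <- function(tags) {
    if (is(tags, "ClipTagSet")) tagSequences(tags, "DNA")
    else if (is(tags, "DNAStringSet")) tags
    else DNAStringSet(rnaToDna(as.character(tags)))
}

#' Exact-match placement of tags on a genome
#'
#' Desk-scale stand-in for an external aligner: exact substring search of
#' both genome strands. Zero hits give status \code{unmapped}, one gives
#' \code{unique} (with coordinates), two or more give \code{multi}.
#' Reverse-strand hits are reported in forward-reference coordinates with
#' strand \code{-}. Tags flagged by \code{contaminants} are reported as
#' status \code{contaminant} and never searched against the genome.
#'
#' @param tags a \linkS4class{ClipTagSet}, \code{DNAStringSet} or character
#'   vector.
#' @param genome a \code{DNAStringSet}.
#' @param contaminants optional logical vector as returned by
#'   \code{\link{flagContaminants}}.
#' @param min_len minimum tag length accepted for mapping.
#' @return \code{DataFrame} with one row per tag: \code{tag_id},
#'   \code{status} (unique/multi/unmapped/contaminant), \code{n_hits}, and
#'   for unique tags \code{chrom}, \code{start}, \code{end} (1-based
#'   inclusive), \code{strand}.
#' @export
mapTagsExact <- function(tags, genome, contaminants = NULL, min_len = 6L) {
    seqs <- tagSeqsAsDNA(tags)
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("tag%04d", seq_along(seqs))
    if (any(width(seqs) < min_len))
        stop("tags shorter than min_len cannot be mapped")
    if (is.null(contaminants)) contaminants <- rep(FALSE, length(seqs))
    status <- character(length(seqs))
    n_hits <- integer(length(seqs))
    chrom <- rep(NA_character_, length(seqs))
    hstart <- rep(NA_integer_, length(seqs))
    hend <- rep(NA_integer_, length(seqs))
    hstrand <- rep(NA_character_, length(seqs))
    for (i in seq_along(seqs)) {
        if (contaminants[i]) {
            status[i] <- "contaminant"
            next
        }
        hits <- genomeHits(seqs[[i]], genome)
        n_hits[i] <- nrow(hits)
        if (nrow(hits) == 0L) {
            status[i] <- "unmapped"
        } else if (nrow(hits) == 1L) {
            status[i] <- "unique"
            chrom[i] <- hits$chrom
            hstart[i] <- hits$start
            hend[i] <- hits$end
            hstrand[i] <- hits$strand
        } else {
            status[i] <- "multi"
        }
    }
    DataFrame(tag_id = ids, status = status, n_hits = n_hits,
              chrom = chrom, start = hstart, end = hend, strand = hstrand)
}

## all exact placements of one tag, both strands, forward coordinates
genomeHits <- function(tag, genome) {
    out <- list()
    rc <- reverseComplement(tag)
    for (ch in names(genome)) {
        m <- matchPattern(tag, genome[[ch]])
        if (length(m))
            out[[length(out) + 1L]] <- data.frame(
                chrom = ch, start = BiocGenerics::start(m),
                end = BiocGenerics::end(m), strand = "+")
        m2 <- matchPattern(rc, genome[[ch]])
        if (length(m2))
            out[[length(out) + 1L]] <- data.frame(
                chrom = ch, start = BiocGenerics::start(m2),
                end = BiocGenerics::end(m2), strand = "-")
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(chrom = character(), start = integer(),
                    end = integer(), strand = character())
}

#' Import tag alignments from a BED6 file
#'
#' Lets external aligner output (e.g. BLAT hits exported as BED) enter the
#' pipeline. BED is 0-based half-open on disk; the returned coordinates are
#' 1-based inclusive, matching \code{\link{mapTagsExact}}. Tags with
#' multiple BED lines get status \code{multi} (no coordinates); tags listed
#' in \code{tag_ids} but absent from the file are \code{unmapped}.
#'
#' @param path BED6 file.
#' @param tag_ids optional character vector of all tag ids, to report
#'   unmapped tags.
#' @param chrom_sizes optional named vector of chromosome lengths for
#'   interval validation.
#' @return \code{DataFrame} with the same columns as
#'   \code{\link{mapTagsExact}}.
#' @export
importAlignments <- function(path, tag_ids = NULL, chrom_sizes = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    recs <- vector("list", length(lines))
    for (ln in seq_along(lines)) {
        f <- strsplit(lines[ln], "\t| +")[[1]]
        if (length(f) < 6L)
            stop("malformed BED line ", ln, ": expected 6 fields, got ",
                 length(f))
        start0 <- suppressWarnings(as.integer(f[2]))
        end0 <- suppressWarnings(as.integer(f[3]))
        if (is.na(start0) || is.na(end0) || start0 >= end0)
            stop("malformed BED line ", ln, ": bad interval")
        if (!f[6] %in% c("+", "-"))
            stop("malformed BED line ", ln, ": bad strand")
        if (!is.null(chrom_sizes)) {
            if (!f[1] %in% names(chrom_sizes))
                stop("malformed BED line ", ln, ": unknown chromosome ",
                     f[1])
            if (end0 > chrom_sizes[[f[1]]])
                stop("malformed BED line ", ln, ": interval beyond ",
                     "chromosome end")
        }
        recs[[ln]] <- data.frame(tag_id = f[4], chrom = f[1],
                                 start = start0 + 1L, end = end0,
                                 strand = f[6], stringsAsFactors = FALSE)
    }
    bed <- do.call(rbind, recs)
    if (is.null(bed))
        bed <- data.frame(tag_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character())
    counts <- table(bed$tag_id)
    ids <- if (is.null(tag_ids)) unique(bed$tag_id) else tag_ids
    res <- DataFrame(tag_id = ids,
                     status = rep("unmapped", length(ids)),
                     n_hits = rep(0L, length(ids)),
                     chrom = rep(NA_character_, length(ids)),
                     start = rep(NA_integer_, length(ids)),
                     end = rep(NA_integer_, length(ids)),
                     strand = rep(NA_character_, length(ids)))
    for (i in seq_along(ids)) {
        k <- counts[ids[i]]
        if (is.na(k) || k == 0L) next
        res$n_hits[i] <- as.integer(k)
        if (k == 1L) {
            j <- which(bed$tag_id == ids[i])
            res$status[i] <- "unique"
            res$chrom[i] <- bed$chrom[j]
            res$start[i] <- bed$start[j]
            res$end[i] <- bed$end[j]
            res$strand[i] <- bed$strand[j]
        } else {
            res$status[i] <- "multi"
        }
    }
    res
}

#' Export unique alignments as BED6
#'
#' @param alignments \code{DataFrame} from \code{\link{mapTagsExact}} or
#'   \code{\link{importAlignments}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAlignmentsBED <- function(alignments, path) {
    u <- alignments[alignments$status == "unique", , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", u$chrom, u$start - 1L,
                     u$end, u$tag_id, u$strand)
    writeLines(lines, path)
    invisible(path)
}

#' Unique alignments as a GRanges
#'
#' @param alignments \code{DataFrame} of per-tag mapping results.
#' @return GRanges with \code{tag_id} metadata column (unique tags only).
#' @export
alignmentsAsGRanges <- function(alignments) {
    u <- alignments[alignments$status == "unique", , drop = FALSE]
    gr <- GRanges(seqnames = u$chrom,
                  ranges = IRanges(start = u$start, end = u$end),
                  strand = u$strand)
    mcols(gr)$tag_id <- u$tag_id
    gr
}

#' Summarize the mapping triage of a tag set
#'
#' Partitions tags into contaminants, unmapped-or-multimapped, and uniquely
#' mapped, with fractions of the total — the triage a CLIP study reports
#' before annotating tags.
#'
#' @param status character vector of per-tag statuses, or the
#'   \code{DataFrame} from \code{\link{mapTagsExact}} /
#'   \code{\link{importAlignments}}.
#' @return list with \code{n_total}, \code{n_contaminant},
#'   \code{n_unmapped_or_multi}, \code{n_unique} and a \code{fractions}
#'   vector summing to 1.
#' @examples
#' summarizeMapping(c(rep("contaminant", 148),
#'                    rep("multi", 197), rep("unique", 219)))
#' @export
summarizeMapping <- function(status) {
    if (is(status, "DataFrame") || is.data.frame(status))
        status <- status$status
    stopifnot(all(status %in% c("unique", "multi", "unmapped",
                                "contaminant")))
    n <- length(status)
    n_contam <- sum(status == "contaminant")
    n_um <- sum(status %in% c("unmapped", "multi"))
    n_unique <- sum(status == "unique")
    fr <- if (n > 0) c(contaminant = n_contam, unmapped_or_multi = n_um,
                       unique = n_unique) / n
          else c(contaminant = 0, unmapped_or_multi = 0, unique = 0)
    list(n_total = n, n_contaminant = n_contam,
         n_unmapped_or_multi = n_um, n_unique = n_unique,
         fractions = fr)
}
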