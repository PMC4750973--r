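#' @importFrom Biostrings matchPattern
NULL

## Hamming-tolerant adapter search on a plain character sequence.
## Returns a two-column matrix of (start, end) matches, ordered by start.
adapterMatches <- function(seq, adapter, max_mismatches = 0L) {
    if (max_mismatches == 0L) {
        ## exact matching via fixed-string search (no XString overhead)
        hits <- gregexpr(adapter, seq, fixed = TRUE)[[1]]
        if (hits[1] == -1L)
            return(cbind(start = integer(0), end = integer(0)))
        starts <- as.integer(hits)
        return(cbind(start = starts, end = starts + nchar(adapter) - 1L))
    }
    m <- matchPattern(adapter, DNAString(seq),
                      max.mismatch = max_mismatches, with.indels = FALSE)
    cbind(start = BiocGenerics::start(m), end = BiocGenerics::end(m))
}

## One-orientation extraction attempt. Leftmost adapter5 / rightmost
## adapter3 pair; additional adapter occurrences strictly inside the
## resulting insert make the clone ambiguous. Reports which adapters were
## seen so the caller can name the rejection.
extractOneOrientation <- function(seq, adapter5, adapter3, max_mismatches) {
    m5 <- adapterMatches(seq, adapter5, max_mismatches)
    m3 <- adapterMatches(seq, adapter3, max_mismatches)
    found5 <- nrow(m5) > 0L
    found3 <- nrow(m3) > 0L
    if (!found5 || !found3)
        return(list(ok = FALSE, found5 = found5, found3 = found3))
    a5 <- m5[1, ]                       # leftmost adapter5
    m3v <- m3[m3[, "start"] > a5["end"], , drop = FALSE]
    if (nrow(m3v) == 0L)
        return(list(ok = FALSE, found5 = TRUE, found3 = TRUE,
                    wrong_orientation = TRUE))
    a3 <- m3v[nrow(m3v), ]              # rightmost adapter3 after it
    ins_lo <- a5["end"] + 1L
    ins_hi <- a3["start"] - 1L
    inner <- function(m) any(m[, "start"] >= ins_lo & m[, "end"] <= ins_hi)
    if (inner(m5) || inner(m3))
        return(list(ok = FALSE, found5 = TRUE, found3 = TRUE,
                    ambiguous = TRUE))
    insert <- substr(seq, ins_lo, ins_hi)
    list(ok = TRUE, insert = insert, found5 = TRUE, found3 = TRUE)
}

#' Extract the insert tag from one clone sequence
#'
#' Searches the clone for the 5' adapter ending before the 3' adapter
#' begins — the correct cloning orientation — and returns the intervening
#' insert with the adapters removed. The forward read is tried first; the
#' reverse complement is searched only when the forward orientation yields
#' no valid insert (Sanger clones are read from either end). If an adapter
#' occurs several times, the leftmost 5' adapter and the rightmost
#' subsequent 3' adapter delimit the insert; any further adapter copy
#' strictly inside that insert leaves the true insert undefined and the
#' clone is rejected as ambiguous.
#'
#' @param sequence clone sequence (character, A/C/G/T/N).
#' @param adapter5,adapter3 adapter sequences (DNA).
#' @param max_mismatches Hamming tolerance for adapter matching (default 0,
#'   exact).
#' @param min_len,max_len accepted insert length bounds (nt);
#'   \code{max_len = Inf} leaves length uncapped above.
#' @param search_rc also search the clone's reverse complement?
#' @return list with \code{accepted} (logical) and either \code{insert}
#'   (character) or \code{reason}, one of \code{no_adapter5},
#'   \code{no_adapter3}, \code{wrong_orientation}, \code{too_short},
#'   \code{too_long}, \code{ambiguous_multiple_placements}.
#' @examples
#' extractTag("GGGACGTACGTACGTACGTCCC", "GGG", "CCC", min_len = 10)
#' @export
extractTag <- function(sequence, adapter5, adapter3, max_mismatches = 0L,
                       min_len = 15L, max_len = Inf, search_rc = TRUE) {
    sequence <- toupper(sequence)
    if (!nzchar(sequence) || grepl("[^ACGTN]", sequence))
        stop("clone sequence must be non-empty over A/C/G/T/N")
    stopifnot(nzchar(adapter5), nzchar(adapter3), max_mismatches >= 0)
    fwd <- extractOneOrientation(sequence, adapter5, adapter3,
                                 max_mismatches)
    if (isTRUE(fwd$ambiguous))
        return(list(accepted = FALSE,
                    reason = "ambiguous_multiple_placements"))
    rev <- if (!fwd$ok && search_rc) {
        rc <- chartr("ACGTN", "TGCAN",
                     intToUtf8(rev(utf8ToInt(sequence))))
        extractOneOrientation(rc, adapter5, adapter3, max_mismatches)
    } else list(ok = FALSE, found5 = FALSE, found3 = FALSE)
    if (isTRUE(rev$ambiguous))
        return(list(accepted = FALSE,
                    reason = "ambiguous_multiple_placements"))
    hit <- if (fwd$ok) fwd else if (rev$ok) rev else NULL
    if (is.null(hit)) {
        ## diagnose from the orientation in which the 5' adapter was seen
        diag <- function(o) {
            if (!o$found5) "no_adapter5"
            else if (!o$found3) "no_adapter3"
            else "wrong_orientation"
        }
        reason <- if (fwd$found5) diag(fwd)
                  else if (rev$found5) diag(rev)
                  else "no_adapter5"
        return(list(accepted = FALSE, reason = reason))
    }
    n <- nchar(hit$insert)
    if (n < min_len) return(list(accepted = FALSE, reason = "too_short"))
    if (n > max_len) return(list(accepted = FALSE, reason = "too_long"))
    list(accepted = TRUE, insert = hit$insert)
}

REJECTION_REASONS <- c("no_adapter5", "no_adapter3", "wrong_orientation",
                       "too_short", "too_long",
                       "ambiguous_multiple_placements")

#' Extract and tabulate distinct tags from a clone library
#'
#' Runs \code{\link{extractTag}} over every clone, then groups the accepted
#' inserts into distinct tag sequences with occurrence counts and source
#' clone ids — "different tags" in the CLIP sense. The
#' extraction report conserves clones: accepted plus every rejection reason
#' sums to the library size.
#'
#' @param clones named \code{DNAStringSet} or named character vector of
#'   clone sequences.
#' @param adapter5,adapter3 adapter sequences.
#' @param ... passed on to \code{\link{extractTag}}
#'   (\code{max_mismatches}, \code{min_len}, \code{max_len},
#'   \code{search_rc}).
#' @return A \linkS4class{ClipTagSet}.
#' @examples
#' cl <- c(c1 = "GGGACGTACGTACGTACGTCCC", c2 = "GGGACGTACGTACGTACGTCCC")
#' tabulateTags(cl, "GGG", "CCC", min_len = 10)
#' @export
tabulateTags <- function(clones, adapter5, adapter3, ...) {
    seqs <- as.character(clones)
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("clone%04d", seq_along(seqs))
    report <- setNames(integer(length(REJECTION_REASONS) + 1L),
                       c("accepted", REJECTION_REASONS))
    inserts <- character(0)
    insert_clone <- character(0)
    for (i in seq_along(seqs)) {
        res <- extractTag(seqs[i], adapter5, adapter3, ...)
        if (res$accepted) {
            report["accepted"] <- report["accepted"] + 1L
            inserts <- c(inserts, res$insert)
            insert_clone <- c(insert_clone, ids[i])
        } else {
            report[res$reason] <- report[res$reason] + 1L
        }
    }
    if (length(inserts)) {
        grp <- split(insert_clone, inserts)
        uniq <- names(grp)
        ord <- order(-lengths(grp), uniq)
        uniq <- uniq[ord]; grp <- grp[ord]
        tags <- DataFrame(sequence = uniq,
                          count = lengths(grp),
                          clone_ids = CharacterList(unname(grp)))
    } else {
        tags <- DataFrame(sequence = character(), count = integer(),
                          clone_ids = CharacterList())
    }
    rownames(tags) <- if (nrow(tags)) sprintf("tag%04d", seq_len(nrow(tags)))
                      else character(0)
    new("ClipTagSet", tags = tags, report = report)
}

#' @describeIn ClipTagSet-class tag sequences, as a \code{DNAStringSet}
#'   (\code{alphabet = "DNA"}) or \code{RNAStringSet} (\code{"RNA"}); tag
#'   counting and motif reporting use the RNA view, storage is DNA.
#' @param alphabet "DNA" or "RNA".
#' @export
tagSequences <- function(x, alphabet = c("DNA", "RNA")) {
    alphabet <- match.arg(alphabet)
    s <- setNames(x@tags$sequence, rownames(x@tags))
    if (alphabet == "DNA") DNAStringSet(s)
    else RNAStringSet(dnaToRna(s))
}

#' @describeIn ClipTagSet-class per-tag occurrence counts (named integer).
#' @export
tagCounts <- function(x) setNames(x@tags$count, rownames(x@tags))

#' @describeIn ClipTagSet-class extraction report: accepted total and
#'   totals per rejection reason.
#' @export
extractionReport <- function(x) x@report
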