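#' @importFrom Biostrings DNAStringSet RNAStringSet DNAString
#'   writeXStringSet readDNAStringSet reverseComplement subseq "subseq<-"
#' @importFrom stats rlnorm runif rbinom qnorm setNames
NULL

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so generator calls do not perturb user code.
withSeed <- function(seed, expr) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
    force(expr)
}

rnaToDna <- function(x) chartr("U", "T", toupper(x))
dnaToRna <- function(x) chartr("T", "U", toupper(x))

#' Generate a random genome
#'
#' Draws each chromosome i.i.d. from the configured base composition under
#' the configuration seed; identical configurations yield byte-identical
#' sequences (and FASTA files, via \code{\link[Biostrings]{writeXStringSet}}).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param path optional FASTA output path.
#' @return A named \code{DNAStringSet} (chr1, chr2, ...).
#' @examples
#' g <- generateGenome(simConfig(seed = 1, chrom_length = 1000L))
#' g
#' @export
generateGenome <- function(config, path = NULL) {
    stopifnot(is(config, "SimConfig"))
    genome <- withSeed(config@seed + 101L, {
        seqs <- vapply(seq_len(config@n_chroms), function(i) {
            paste(sample(c("A", "C", "G", "T"), config@chrom_length,
                         replace = TRUE, prob = config@base_composition),
                  collapse = "")
        }, character(1))
        DNAStringSet(setNames(seqs, paste0("chr", seq_len(config@n_chroms))))
    })
    if (!is.null(path)) writeXStringSet(genome, path)
    genome
}

#' Sample intron lengths from the heavy-tailed law
#'
#' Log-normal lengths parameterised by the median and the fraction of mass
#' above a "large intron" cutoff: \code{meanlog = log(median)} and
#' \code{sdlog = (log(cutoff) - log(median)) / qnorm(1 - frac)}. Draws are
#' rounded to integers, floored at 60 nt (a plausible minimal intron) and,
#' to keep synthetic genes placeable, capped at \code{cap} by resampling
#' (the cap is far in the tail at the default parameters).
#'
#' @param n number of introns.
#' @param median median intron length (nt).
#' @param cutoff,frac the law places \code{frac} of its mass above
#'   \code{cutoff}.
#' @param cap resampling cap (nt).
#' @return integer vector of lengths.
#' @export
sampleIntronLengths <- function(n, median = 3000, cutoff = 10000,
                                frac = 0.15, cap = 100000) {
    stopifnot(cutoff > median, frac > 0, frac < 0.5)
    sdlog <- (log(cutoff) - log(median)) / qnorm(1 - frac)
    len <- as.integer(round(rlnorm(n, meanlog = log(median), sdlog = sdlog)))
    for (it in 1:50) {
        bad <- len < 60L | len > cap
        if (!any(bad)) break
        len[bad] <- as.integer(round(rlnorm(sum(bad), log(median), sdlog)))
    }
    pmin(pmax(len, 60L), as.integer(cap))
}

#' Generate non-overlapping gene models on a genome
#'
#' Each gene has a 5'UTR-bearing first exon, at least two coding exons and a
#' 3'UTR-bearing last exon; intron lengths are drawn from the heavy-tailed
#' law in \code{config}; a configured fraction of genes is flagged "unknown".
#' Genes are placed sequentially with random intergenic gaps and never
#' overlap. Fails with a sizing error when the genome cannot hold the
#' requested genes.
#'
#' @param genome a \code{DNAStringSet}.
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{GeneModels} object.
#' @export
generateGeneModels <- function(genome, config) {
    stopifnot(is(config, "SimConfig"))
    withSeed(config@seed + 202L, {
        for (attempt in 1:20) {
            mdl <- try(placeGenesOnce(genome, config), silent = TRUE)
            if (!inherits(mdl, "try-error")) return(mdl)
        }
        stop("genome too small for the requested gene models: ",
             attr(mdl, "condition")$message)
    })
}

placeGenesOnce <- function(genome, config) {
    n <- config@n_genes
    chrom_len <- width(genome)
    n_exons <- sample(seq(config@min_exons, config@min_exons + 2L),
                      n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    min_gap <- 200L
    structures <- vector("list", n)
    for (i in seq_len(n)) {
        ne <- n_exons[i]
        wid <- rep(config@cds_exon_len, ne)
        wid[1] <- wid[1] + if (strands[i] == "+") config@utr5_len else config@utr3_len
        wid[ne] <- wid[ne] + if (strands[i] == "+") config@utr3_len else config@utr5_len
        intr <- sampleIntronLengths(ne - 1L, config@intron_median,
                                    config@intron_large_cutoff,
                                    config@intron_large_frac,
                                    cap = max(chrom_len) / 20)
        structures[[i]] <- list(widths = wid, introns = intr,
                                len = sum(wid) + sum(intr))
    }
    lens <- vapply(structures, `[[`, numeric(1), "len")
    ## greedy assignment of genes to chromosomes
    chrom_of <- integer(n)
    cursor <- rep(1L, length(genome))
    order_idx <- seq_len(n)
    starts <- integer(n)
    for (i in order_idx) {
        placed <- FALSE
        for (ch in seq_along(genome)) {
            gap <- min_gap + sample.int(2000L, 1L)
            if (cursor[ch] + gap + lens[i] <= chrom_len[ch]) {
                starts[i] <- cursor[ch] + gap
                chrom_of[i] <- ch
                cursor[ch] <- starts[i] + as.integer(lens[i])
                placed <- TRUE
                break
            }
        }
        if (!placed) stop("gene ", i, " does not fit")
    }
    ids <- sprintf("gene%03d", seq_len(n))
    exons <- vector("list", n)
    cds <- vector("list", n)
    for (i in seq_len(n)) {
        st <- structures[[i]]
        ex_start <- starts[i] + cumsum(c(0L, head(st$widths, -1) +
                                             st$introns))
        ex_end <- ex_start + st$widths - 1L
        exons[[i]] <- GRanges(
            seqnames = names(genome)[chrom_of[i]],
            ranges = IRanges(start = ex_start, end = ex_end),
            strand = strands[i])
        gene_start <- ex_start[1]
        gene_end <- ex_end[length(ex_end)]
        if (strands[i] == "+") {
            cds_se <- c(gene_start + config@utr5_len,
                        gene_end - config@utr3_len)
        } else {
            cds_se <- c(gene_start + config@utr3_len,
                        gene_end - config@utr5_len)
        }
        cds[[i]] <- GRanges(seqnames = names(genome)[chrom_of[i]],
                            ranges = IRanges(start = cds_se[1],
                                             end = cds_se[2]),
                            strand = strands[i])
    }
    exons <- GRangesList(setNames(exons, ids))
    cds <- setNames(unlist(GRangesList(cds)), ids)
    known <- setNames(runif(n) >= config@unknown_frac, ids)
    geneModels(exons, cds, known)
}

#' Plant motif binding sites into introns
#'
#' Writes \code{n_sites} copies of the configured motif (DNA alphabet, on
#' the forward genome strand) at positions drawn uniformly over all eligible
#' intronic offsets, without overlap between sites. Overwriting preserves
#' genome length. Recorded intervals are the planted-truth used by
#' downstream recovery tests.
#'
#' @param genome a \code{DNAStringSet}.
#' @param models a \linkS4class{GeneModels}.
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{genome} (modified \code{DNAStringSet}) and
#'   \code{sites} (GRanges with a \code{gene_id} metadata column).
#' @export
plantBindingSites <- function(genome, models, config) {
    motif_dna <- rnaToDna(config@motif)
    mlen <- nchar(motif_dna)
    introns <- intronBlocks(models)
    flat <- unlist(introns, use.names = FALSE)
    gene_of <- rep(names(introns), lengths(introns))
    ok <- width(flat) >= mlen
    flat <- flat[ok]; gene_of <- gene_of[ok]
    if (config@n_sites == 0L)
        return(list(genome = genome,
                    sites = GRanges(gene_id = character())))
    capacity <- sum(width(flat) - mlen + 1)
    if (capacity < config@n_sites * mlen)
        stop("more sites than intronic capacity")
    withSeed(config@seed + 303L, {
        chosen <- GRanges()
        chosen_gene <- character()
        guard <- 0L
        while (length(chosen) < config@n_sites) {
            guard <- guard + 1L
            if (guard > 50L * config@n_sites)
                stop("could not place ", config@n_sites,
                     " non-overlapping sites")
            j <- sample.int(length(flat), 1L,
                            prob = width(flat) - mlen + 1)
            off <- sample.int(width(flat)[j] - mlen + 1L, 1L)
            cand <- GRanges(seqnames = seqnames(flat)[j],
                            ranges = IRanges(start = start(flat)[j] + off - 1L,
                                             width = mlen),
                            strand = "*")
            if (length(chosen) == 0L ||
                !any(IRanges::overlapsAny(cand, chosen,
                                          ignore.strand = TRUE))) {
                chosen <- c(chosen, cand)
                chosen_gene <- c(chosen_gene, gene_of[j])
            }
        }
        for (i in seq_along(chosen)) {
            ch <- as.character(seqnames(chosen)[i])
            subseq(genome[[ch]], start = start(chosen)[i],
                   end = end(chosen)[i]) <- DNAString(motif_dna)
        }
        mcols(chosen)$gene_id <- chosen_gene
        list(genome = genome, sites = sort(chosen))
    })
}

#' Deterministic contaminant reference sequence
#'
#' A bacterial-rRNA-like reference: a single 5 kb GC-rich sequence derived
#' from the configuration seed, used both to draw contaminant clone inserts
#' and as the screening reference for \code{\link{flagContaminants}}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \code{DNAStringSet} of length 1 named "contam_rRNA".
#' @export
contaminantReference <- function(config) {
    withSeed(config@seed + 404L, {
        s <- paste(sample(c("A", "C", "G", "T"), 5000L, replace = TRUE,
                          prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
        DNAStringSet(c(contam_rRNA = s))
    })
}

#' Simulate a CLIP clone library with known truth
#'
#' Each clone is assigned an origin (planted site, genomic background,
#' contaminant, malformed) with the configured probabilities. Well-formed
#' clones are \code{adapter5 + insert + adapter3}, optionally emitted
#' reverse-complemented with probability 0.5; site-derived inserts are
#' forward-strand genomic windows fully covering a planted motif;
#' contaminant inserts are substrings of the contaminant reference;
#' malformed clones lack an adapter or carry them in the wrong orientation.
#' The truth manifest records every clone exactly once.
#'
#' @param genome a \code{DNAStringSet} (with sites already planted).
#' @param sites GRanges of planted sites (from
#'   \code{\link{plantBindingSites}}).
#' @param config a \linkS4class{SimConfig}.
#' @param path optional clone FASTA output path.
#' @return list with \code{clones} (named \code{DNAStringSet}),
#'   \code{truth} (data.frame: clone_id, origin, insert, chrom, start, end)
#'   and \code{contaminant_ref} (\code{DNAStringSet}).
#' @export
simulateClipClones <- function(genome, sites, config, path = NULL) {
    stopifnot(is(config, "SimConfig"))
    if (config@tag_max_len < config@tag_min_len)
        stop("tag length law: max < min")
    contam <- contaminantReference(config)
    contam_seq <- as.character(contam[[1]])
    chrom_len <- setNames(width(genome), names(genome))
    withSeed(config@seed + 505L, {
        n <- config@n_clones
        origin <- sample(c("site", "contaminant", "malformed", "background"),
                         n, replace = TRUE,
                         prob = c(config@site_tag_rate,
                                  config@contaminant_rate,
                                  config@malformed_rate,
                                  max(0, 1 - config@site_tag_rate -
                                          config@contaminant_rate -
                                          config@malformed_rate)))
        if (length(sites) == 0L) origin[origin == "site"] <- "background"
        L <- sample(seq(config@tag_min_len, config@tag_max_len), n,
                    replace = TRUE)
        insert <- character(n)
        chrom <- rep(NA_character_, n)
        gstart <- rep(NA_integer_, n)
        ids <- sprintf("clone%04d", seq_len(n))
        for (i in seq_len(n)) {
            if (origin[i] %in% c("site")) {
                j <- sample.int(length(sites), 1L)
                ch <- as.character(seqnames(sites)[j])
                ## any window overlapping the planted site (>= 1 nt)
                lo <- max(1L, start(sites)[j] - L[i] + 1L)
                hi <- min(end(sites)[j], chrom_len[ch] - L[i] + 1L)
                st <- if (hi <= lo) lo else sample(seq(lo, hi), 1L)
                insert[i] <- as.character(subseq(genome[[ch]], st,
                                                 st + L[i] - 1L))
                chrom[i] <- ch; gstart[i] <- st
            } else if (origin[i] == "contaminant") {
                st <- sample.int(nchar(contam_seq) - L[i] + 1L, 1L)
                insert[i] <- substr(contam_seq, st, st + L[i] - 1L)
            } else {
                ch <- sample(names(genome), 1L)
                st <- sample.int(chrom_len[ch] - L[i] + 1L, 1L)
                insert[i] <- as.character(subseq(genome[[ch]], st,
                                                 st + L[i] - 1L))
                chrom[i] <- ch; gstart[i] <- st
            }
        }
        clone_seq <- character(n)
        malform_kind <- rep(NA_character_, n)
        for (i in seq_len(n)) {
            if (origin[i] == "malformed") {
                malform_kind[i] <- sample(c("no_adapter5", "no_adapter3",
                                            "swapped"), 1L)
                clone_seq[i] <- switch(malform_kind[i],
                    no_adapter5 = paste0(insert[i], config@adapter3),
                    no_adapter3 = paste0(config@adapter5, insert[i]),
                    swapped = paste0(config@adapter3, insert[i],
                                     config@adapter5))
            } else {
                clone_seq[i] <- paste0(config@adapter5, insert[i],
                                       config@adapter3)
            }
            if (config@rc_clones && runif(1) < 0.5)
                clone_seq[i] <- as.character(
                    reverseComplement(DNAString(clone_seq[i])))
        }
        clones <- DNAStringSet(setNames(clone_seq, ids))
        if (!is.null(path)) writeXStringSet(clones, path)
        truth <- data.frame(
            clone_id = ids, origin = origin, insert = insert,
            malform_kind = malform_kind,
            chrom = chrom, start = gstart,
            end = ifelse(is.na(gstart), NA_integer_, gstart + L - 1L),
            stringsAsFactors = FALSE)
        list(clones = clones, truth = truth, contaminant_ref = contam)
    })
}

#' Simulate a two-condition differential-expression table
#'
#' Generates FPKM-like expression for control and knockdown conditions with
#' known per-gene categories: \code{shared_down}/\code{shared_up} genes have
#' absolute fold changes at or above \code{min_fold} (drawn as
#' \code{min_fold * exp(Exp(rate))}, so the fraction exceeding 2-fold is
#' tunable per direction), \code{only_control}/\code{only_kd} genes have
#' expression exactly 0 in the other condition, and the remainder are
#' unchanged (|fold| < \code{min_fold}, not significant). All non-unchanged
#' genes carry a significance flag.
#'
#' @param n_genes number of genes.
#' @param frac_down,frac_up fractions of shared down-/up-regulated genes.
#' @param frac_only_control,frac_only_kd fractions expressed in one
#'   condition only.
#' @param min_fold minimum absolute fold change for regulated genes.
#' @param down_rate,up_rate exponential rates for the log-fold excess above
#'   \code{min_fold}; defaults put roughly one third of down-regulated and
#'   two thirds of up-regulated genes beyond 2-fold, the asymmetry seen in
#'   knockdown transcriptomes where induced genes move further than
#'   repressed ones.
#' @param seed integer seed.
#' @param path optional TSV output path.
#' @return list with \code{table} (data.frame: gene_id, expr_control,
#'   expr_kd, significant) and \code{truth} (data.frame: gene_id, category,
#'   true_fold).
#' @export
simulateDeTable <- function(n_genes = 2000L, frac_down = 0.25,
                            frac_up = 0.18, frac_only_control = 0.02,
                            frac_only_kd = 0.10, min_fold = 1.5,
                            down_rate = 3.8, up_rate = 1.4,
                            seed = 1L, path = NULL) {
    stopifnot(frac_down + frac_up + frac_only_control + frac_only_kd <= 1)
    withSeed(seed + 606L, {
        n_down <- round(n_genes * frac_down)
        n_up <- round(n_genes * frac_up)
        n_oc <- round(n_genes * frac_only_control)
        n_ok <- round(n_genes * frac_only_kd)
        n_un <- n_genes - n_down - n_up - n_oc - n_ok
        category <- sample(rep(c("shared_down", "shared_up", "only_control",
                                 "only_kd", "unchanged"),
                               c(n_down, n_up, n_oc, n_ok, n_un)))
        base <- rlnorm(n_genes, meanlog = log(20), sdlog = 1)
        expr_control <- base
        expr_kd <- base
        true_fold <- rep(1, n_genes)
        i <- category == "shared_down"
        true_fold[i] <- min_fold * exp(stats::rexp(sum(i), down_rate))
        expr_kd[i] <- base[i] / true_fold[i]
        i <- category == "shared_up"
        true_fold[i] <- min_fold * exp(stats::rexp(sum(i), up_rate))
        expr_kd[i] <- base[i] * true_fold[i]
        i <- category == "only_control"
        expr_kd[i] <- 0
        i <- category == "only_kd"
        expr_control[i] <- 0
        i <- category == "unchanged"
        r <- runif(sum(i), 1, min(min_fold, 1.3))
        dirn <- sample(c(TRUE, FALSE), sum(i), replace = TRUE)
        expr_kd[i] <- ifelse(dirn, base[i] * r * 0.999, base[i] / r)
        if (any(expr_control < 0) || any(expr_kd < 0))
            stop("negative expression generated")
        tab <- data.frame(
            gene_id = sprintf("g%05d", seq_len(n_genes)),
            expr_control = expr_control, expr_kd = expr_kd,
            significant = category != "unchanged",
            stringsAsFactors = FALSE)
        truth <- data.frame(gene_id = tab$gene_id, category = category,
                            true_fold = true_fold, stringsAsFactors = FALSE)
        if (!is.null(path))
            utils::write.table(tab, path, sep = "\t", quote = FALSE,
                               row.names = FALSE)
        list(table = tab, truth = truth)
    })
}
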