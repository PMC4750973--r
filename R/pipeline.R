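#' Run the full synthetic CLIP analysis pipeline
#'
#' Orchestrates every stage from one configuration: genome and gene-model
#' simulation, binding-site planting, clone library simulation, adapter
#' trimming and tag tabulation, contaminant screening, exact-match genome
#' placement, gene-context annotation, intron geometry, and 1-6-mer
#' incidence with per-tag motif distributions. Deterministic for a fixed
#' configuration; every number in the machine-readable summary is
#' recomputable by calling the underlying stage functions directly.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param out_dir optional directory for file outputs (FASTA, BED, TSV,
#'   JSON summary and figure PNGs); nothing is written when NULL.
#' @param kmer_k k-mer sizes to tabulate (default \code{c(2, 6)}).
#' @param proximity_threshold splice-site proximity threshold in nt.
#' @param length_bounds intron-length bin bounds in nt.
#' @param verbose emit stage-level progress to stderr?
#' @return list with \code{truth}, \code{tags} (ClipTagSet),
#'   \code{alignments}, \code{mapping_summary}, \code{assignments},
#'   \code{category_fractions}, \code{contexts}, \code{geometry},
#'   \code{proximity}, \code{length_bins}, \code{kmers} (per k),
#'   \code{motif_distributions} (UG and CA), and \code{summary} (flat,
#'   JSON-ready).
#' @export
runClipPipeline <- function(config, out_dir = NULL, kmer_k = c(2, 6),
                            proximity_threshold = 500,
                            length_bounds = c(10000, 100000),
                            verbose = FALSE) {
    say <- function(...) if (verbose) message("[clipscape] ", ...)
    stage <- function(name, expr) {
        say(name)
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    genome <- stage("simulate genome", generateGenome(config))
    models <- stage("simulate gene models",
                    generateGeneModels(genome, config))
    planted <- stage("plant binding sites",
                     plantBindingSites(genome, models, config))
    genome <- planted$genome
    sim <- stage("simulate clone library",
                 simulateClipClones(genome, planted$sites, config))
    tags <- stage("extract and tabulate tags",
                  tabulateTags(sim$clones, config@adapter5,
                               config@adapter3,
                               min_len = min(15L, config@tag_min_len)))
    contam <- stage("screen contaminants",
                    flagContaminants(tags, sim$contaminant_ref))
    aln <- stage("map tags",
                 mapTagsExact(tags, genome, contaminants = contam))
    mapping <- summarizeMapping(aln)
    assignments <- stage("assign gene context",
                         assignGeneContext(aln, models))
    frac <- categoryFractions(assignments)
    contexts <- stage("intron geometry",
                      locateContainingIntron(aln, models, assignments))
    geometry <- if (nrow(contexts)) summarizeGeometry(contexts) else NULL
    prox <- proximityFractions(contexts, proximity_threshold)
    bins <- if (nrow(contexts)) lengthBins(contexts, length_bounds)
            else NULL
    kmers <- stage("k-mer incidence", {
        ks <- sort(unique(as.integer(kmer_k)))
        setNames(lapply(ks, function(k) countKmers(tags, k)),
                 paste0("k", ks))
    })
    motifs <- stage("motif distributions", list(
        UG = motifCountDistribution(tags, "UG"),
        CA = motifCountDistribution(tags, "CA")))
    summary <- list(
        seed = config@seed,
        n_clones = config@n_clones,
        n_accepted = unname(extractionReport(tags)["accepted"]),
        n_distinct_tags = length(tags),
        mapping = mapping[c("n_total", "n_contaminant",
                            "n_unmapped_or_multi", "n_unique")],
        within_gene_fractions = as.list(frac),
        n_intronic_contexts = nrow(contexts),
        proximity = as.list(prox),
        length_bins = if (is.null(bins)) NULL else as.list(bins))
    result <- list(truth = sim$truth, models = models, sites = planted$sites,
                   tags = tags, alignments = aln,
                   mapping_summary = mapping, assignments = assignments,
                   category_fractions = frac, contexts = contexts,
                   geometry = geometry, proximity = prox,
                   length_bins = bins, kmers = kmers,
                   motif_distributions = motifs, summary = summary)
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        writeXStringSet(genome, file.path(out_dir, "genome.fa"))
        writeXStringSet(sim$clones, file.path(out_dir, "clones.fa"))
        writeXStringSet(tagSequences(tags),
                        file.path(out_dir, "tags.fa"))
        writeGeneModelsBED(models, file.path(out_dir, "genes.bed"))
        writeGeneModelsGTF(models, file.path(out_dir, "genes.gtf"))
        writeAlignmentsBED(aln, file.path(out_dir, "alignments.bed"))
        utils::write.table(contexts,
                           file.path(out_dir, "intron_contexts.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(assignments,
                           file.path(out_dir, "assignments.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        grDevices::png(file.path(out_dir, "kmer_incidence.png"),
                       width = 900, height = 500)
        plotKmerIncidence(kmers[[length(kmers)]])
        grDevices::dev.off()
        grDevices::png(file.path(out_dir, "motif_histograms.png"),
                       width = 700, height = 500)
        plotMotifHistograms(tags)
        grDevices::dev.off()
    }
    result
}
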