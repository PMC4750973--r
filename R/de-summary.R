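#' Categorize a two-condition differential-expression table
#'
#' Applies fold-change and significance thresholds to per-gene expression
#' in a control and a knockdown condition. Only significant records are
#' categorized. A gene expressed above \code{floor} in both conditions is
#' \code{shared_down} when \code{expr_control / expr_kd >= fold_threshold}
#' (and symmetrically \code{shared_up}); genes at or below the floor in
#' exactly one condition are \code{only_control} / \code{only_kd} and count
#' toward down-/up-regulation respectively. The strong subsets use a strict
#' inequality at \code{strong_threshold} ("more than" so-many-fold).
#'
#' @param records data.frame with columns \code{gene_id},
#'   \code{expr_control}, \code{expr_kd} (non-negative, FPKM-like) and
#'   logical \code{significant}.
#' @param fold_threshold minimum absolute fold change, inclusive
#'   (default 1.5).
#' @param strong_threshold strong-change threshold, exclusive (default 2).
#' @param floor expression at or below this value counts as not expressed
#'   (default 0, i.e. exactly zero; raise for FPKM noise).
#' @return list with \code{summary} (named integer vector: \code{n_down},
#'   \code{n_up}, \code{n_only_control}, \code{n_only_kd},
#'   \code{n_shared_down}, \code{n_shared_up}, \code{n_shared_down_ge2},
#'   \code{n_shared_up_ge2}) and \code{categories} (per-gene data.frame
#'   with \code{gene_id}, \code{category}, \code{fold_change}).
#' @examples
#' df <- data.frame(gene_id = c("a", "b"), expr_control = c(10, 10),
#'                  expr_kd = c(4, 0), significant = TRUE)
#' categorizeDe(df)$summary
#' @export
categorizeDe <- function(records, fold_threshold = 1.5,
                         strong_threshold = 2.0, floor = 0) {
    stopifnot(fold_threshold > 1, strong_threshold > 1, floor >= 0)
    need <- c("gene_id", "expr_control", "expr_kd", "significant")
    if (!all(need %in% colnames(records)))
        stop("records must have columns ", paste(need, collapse = ", "))
    if (any(records$expr_control < 0) || any(records$expr_kd < 0))
        stop("expression values must be non-negative")
    a <- records$expr_control
    b <- records$expr_kd
    sig <- as.logical(records$significant)
    cat <- rep("unchanged", nrow(records))
    fold <- rep(NA_real_, nrow(records))
    both <- a > floor & b > floor
    fold[both] <- pmax(a[both] / b[both], b[both] / a[both]) *
        ifelse(a[both] >= b[both], -1, 1)   # sign: − means down in kd
    i <- sig & both & a / b >= fold_threshold
    cat[i] <- "shared_down"
    i <- sig & both & b / a >= fold_threshold
    cat[i] <- "shared_up"
    i <- sig & a > floor & b <= floor
    cat[i] <- "only_control"
    i <- sig & b > floor & a <= floor
    cat[i] <- "only_kd"
    summary <- c(
        n_down = sum(cat %in% c("shared_down", "only_control")),
        n_up = sum(cat %in% c("shared_up", "only_kd")),
        n_only_control = sum(cat == "only_control"),
        n_only_kd = sum(cat == "only_kd"),
        n_shared_down = sum(cat == "shared_down"),
        n_shared_up = sum(cat == "shared_up"),
        n_shared_down_ge2 = sum(cat == "shared_down" &
                                    -fold > strong_threshold, na.rm = TRUE),
        n_shared_up_ge2 = sum(cat == "shared_up" &
                                  fold > strong_threshold, na.rm = TRUE))
    list(summary = summary,
         categories = data.frame(gene_id = records$gene_id,
                                 category = cat, fold_change = fold,
                                 stringsAsFactors = FALSE))
}

#' Read a differential-expression table from TSV
#'
#' Expects a header with \code{gene_id}, \code{expr_control},
#' \code{expr_kd}, \code{significant} (and optionally \code{q_value}).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readDeTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "expr_control", "expr_kd", "significant")
    if (!all(need %in% colnames(tab)))
        stop("DE table must have columns ", paste(need, collapse = ", "))
    tab$significant <- as.logical(tab$significant)
    tab
}

#' Write a DE categorization report
#'
#' Writes the per-gene categories as TSV and the count summary as JSON;
#' \code{readDeReport} round-trips them losslessly.
#'
#' @param result list from \code{\link{categorizeDe}}.
#' @param tsv_path per-gene TSV output path.
#' @param json_path summary JSON output path.
#' @return invisibly, \code{result}.
#' @export
writeDeReport <- function(result, tsv_path, json_path) {
    utils::write.table(result$categories, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(result$summary), json_path,
                         auto_unbox = TRUE, digits = NA)
    invisible(result)
}

#' @rdname writeDeReport
#' @export
readDeReport <- function(tsv_path, json_path) {
    categories <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
    summary <- unlist(jsonlite::read_json(json_path, simplifyVector = TRUE))
    list(summary = summary[c("n_down", "n_up", "n_only_control",
                             "n_only_kd", "n_shared_down", "n_shared_up",
                             "n_shared_down_ge2", "n_shared_up_ge2")],
         categories = categories)
}
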