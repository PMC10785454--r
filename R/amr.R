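#' Build a resistance gene catalogue
#'
#' Bundles gene sequences, a gene-to-phenotype map and the antimicrobial
#' panel the predictions range over. When no panel is given it is taken as
#' the union of mapped antimicrobials; the conventional full panel holds 84
#' antimicrobials and combinations.
#'
#' @param genes Named character vector of gene sequences.
#' @param phenotype_map Named list: gene id -> character vector of
#'   antimicrobial names.
#' @param panel Ordered character vector of antimicrobial names.
#' @return A `gene_catalogue` object.
#' @export
gene_catalogue <- function(genes, phenotype_map, panel = NULL) {
  stopifnot(!is.null(names(genes)), all(nchar(genes) > 0))
  if (!all(names(phenotype_map) %in% names(genes))) {
    stop("phenotype_map references unknown genes")
  }
  if (is.null(panel)) panel <- sort(unique(unlist(phenotype_map)))
  extra <- setdiff(unlist(phenotype_map), panel)
  if (length(extra)) {
    stop("phenotype antimicrobial not in panel: ", extra[1])
  }
  structure(list(genes = genes, phenotype_map = phenotype_map, panel = panel),
            class = "gene_catalogue")
}

#' Read a gene catalogue from FASTA + phenotype TSV
#'
#' The phenotype map dialect is `gene_id<TAB>antimicrobial[;antimicrobial...]`;
#' an optional panel file lists one antimicrobial per line.
#'
#' @param fasta Gene FASTA path.
#' @param phenotype_tsv Phenotype map TSV path.
#' @param panel_file Optional panel file path.
#' @return A [gene_catalogue()] object.
#' @export
read_gene_catalogue <- function(fasta, phenotype_tsv, panel_file = NULL) {
  genes <- read_fasta(fasta)
  tab <- utils::read.table(phenotype_tsv, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  pm <- strsplit(tab[[2]], ";", fixed = TRUE)
  names(pm) <- tab[[1]]
  panel <- if (!is.null(panel_file)) readLines(panel_file) else NULL
  gene_catalogue(genes, pm, panel)
}

#' Default 84-slot antimicrobial panel
#'
#' Generic antimicrobial slot names used when no phenotype table supplies a
#' real panel; the size matches the full prediction panel of 84
#' antimicrobials and combinations.
#'
#' @param n Panel size (default 84).
#' @return Character vector of panel names.
#' @export
default_panel <- function(n = 84) sprintf("antimicrobial_%02d", seq_len(n))

#' Screen sequences against a gene catalogue
#'
#' A gene is reported in a target when some chained alignment reaches
#' `min_identity` percent identity and covers at least `min_coverage`
#' percent of the gene length (both inclusive); one best hit is kept per
#' gene per target. Defaults follow the conventional resistance-screening
#' thresholds of 90 percent identity and 60 percent coverage.
#'
#' @param sequences Named character vector of target sequences (a genome or
#'   the scaffolds of a bin).
#' @param catalogue A [gene_catalogue()].
#' @param min_identity,min_coverage Reporting thresholds (percent).
#' @param anchor_k Anchor length for the aligner (default 15; catalogue
#'   genes are short, so anchors are denser than for genome ANI).
#' @return data.frame `gene_id`, `target_id`, `identity`, `coverage`.
#' @export
screen_genes <- function(sequences, catalogue, min_identity = 90,
                         min_coverage = 60, anchor_k = 15) {
  stopifnot(inherits(catalogue, "gene_catalogue"))
  if (!length(catalogue$genes)) stop("empty catalogue")
  out <- list()
  for (g in names(catalogue$genes)) {
    gene <- catalogue$genes[[g]]
    hits <- align_sequences(query = sequences,
                            ref = stats::setNames(gene, g),
                            anchor_k = anchor_k)
    if (!nrow(hits)) next
    for (t in unique(hits$query_id)) {
      sel <- select_consistent_hits(hits[hits$query_id == t, , drop = FALSE])
      cov <- 100 * interval_union_length(sel$ref_start, sel$ref_end) /
        nchar(gene)
      ident <- sum(sel$length * sel$identity) / sum(sel$length)
      if (ident >= min_identity && cov >= min_coverage) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, target_id = t, identity = ident, coverage = cov,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), target_id = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Turn detected genes into a predicted resistance profile
#'
#' @param hits A [screen_genes()] result for one target.
#' @param catalogue A [gene_catalogue()].
#' @return A `resistance_profile`: list with `resistant` (subset of the
#'   panel) and `panel`.
#' @export
genes_to_profile <- function(hits, catalogue) {
  stopifnot(inherits(catalogue, "gene_catalogue"))
  unknown <- setdiff(hits$gene_id, names(catalogue$genes))
  if (length(unknown)) stop("hit references unknown gene: ", unknown[1])
  resistant <- sort(unique(unlist(catalogue$phenotype_map[hits$gene_id])))
  if (is.null(resistant)) resistant <- character(0)
  structure(list(resistant = resistant, panel = catalogue$panel),
            class = "resistance_profile")
}

#' Resistance-prediction concordance between a MAG and its source
#'
#' Per antimicrobial in the panel: TP when both profiles predict
#' resistance, FN when only the source does, FP when only the MAG does, TN
#' otherwise. Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP), accuracy = (TP+TN)/panel,
#' F = 2*precision*sensitivity/(precision+sensitivity); any 0/0 is `NA`.
#'
#' @param mag_profile,source_profile [genes_to_profile()] results (or lists
#'   with a `resistant` character vector).
#' @param panel Antimicrobial panel both profiles range over.
#' @return A `concordance_metrics` list: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `precision`, `f_score`.
#' @export
concordance <- function(mag_profile, source_profile,
                        panel = source_profile$panel) {
  mag <- mag_profile$resistant
  src <- source_profile$resistant
  if (length(setdiff(mag, panel)) || length(setdiff(src, panel))) {
    stop("profile contains antimicrobials outside the panel")
  }
  tp <- length(intersect(mag, src))
  fp <- length(setdiff(mag, src))
  fn <- length(setdiff(src, mag))
  tn <- length(panel) - tp - fp - fn
  metrics_from_counts(tp, fp, tn, fn)
}

metrics_from_counts <- function(tp, fp, tn, fn) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  acc <- ratio(tp + tn, tp + fp + tn + fn)
  f <- if (is.na(sens) || is.na(prec) || (sens + prec) == 0) NA_real_ else {
    2 * prec * sens / (prec + sens)
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, sensitivity = sens,
                 specificity = spec, accuracy = acc, precision = prec,
                 f_score = f),
            class = "concordance_metrics")
}

#' Community-level concordance by pooled confusion counts
#'
#' Pools TP/FP/TN/FN over the evaluated matched source-bin pairs
#' (micro-averaging) and computes one set of metrics per community.
#'
#' @param pair_metrics List of [concordance()] results, one per evaluated
#'   matched pair (unmatched sources contribute nothing).
#' @return A `concordance_metrics` from the pooled counts; all-`NA` metrics
#'   with zero counts when the list is empty.
#' @export
community_concordance <- function(pair_metrics) {
  tp <- sum(vapply(pair_metrics, `[[`, 0, "tp"))
  fp <- sum(vapply(pair_metrics, `[[`, 0, "fp"))
  tn <- sum(vapply(pair_metrics, `[[`, 0, "tn"))
  fn <- sum(vapply(pair_metrics, `[[`, 0, "fn"))
  metrics_from_counts(tp, fp, tn, fn)
}
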