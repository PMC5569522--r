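# DMR annotation: CpG density and flank-based gene association.

#' Count CpG dinucleotides
#'
#' Number of `"CG"` occurrences in each sequence (case-insensitive; `N`
#' never matches). The motif cannot overlap itself, so a plain substring
#' count is exact.
#'
#' @param x Character vector of DNA sequences over `A/C/G/T/N`.
#' @return Integer vector of CpG counts.
#' @examples
#' cpg_count(c("ACGCGT", "AAAA"))
#' @export
cpg_count <- function(x) {
  as.integer(str_count(str_to_upper(x), fixed("CG")))
}

# extract [start, end) (0-based half-open) from a genome's sequence
genome_subseq <- function(genome, chrom, start, end) {
  if (!inherits(genome, "medip_genome") || is.null(genome$sequence)) {
    abort("`genome` must be a medip_genome with sequence.")
  }
  idx <- match(chrom, genome$chromosomes$chrom)
  if (anyNA(idx)) abort("interval on unknown chromosome.")
  len <- genome$chromosomes$length[idx]
  if (any(start < 0 | end > len | start >= end)) {
    abort("interval outside the chromosome sequence.")
  }
  substring(genome$sequence[chrom], start + 1, end)
}

#' Annotate regions with CpG count and density class
#'
#' Adds `cpg_count`, `cpg_density` (CpG per 100 bp over the full region
#' span) and `density_class` (`floor(cpg_density)`; class 0 collects all
#' regions below 1 CpG / 100 bp — the "CpG desert" class) to each region.
#'
#' @param dmrs Region tibble with `chrom`, `start`, `end` (e.g. from
#'   [call_dmrs()]).
#' @param genome `medip_genome` with sequence covering the regions.
#' @return `dmrs` with the three annotation columns appended.
#' @export
annotate_cpg_density <- function(dmrs, genome) {
  if (nrow(dmrs) == 0) {
    return(mutate(dmrs, cpg_count = integer(), cpg_density = numeric(),
                  density_class = integer()))
  }
  n_cpg <- cpg_count(genome_subseq(genome, dmrs$chrom, dmrs$start, dmrs$end))
  len <- dmrs$end - dmrs$start
  dmrs |>
    mutate(
      cpg_count = n_cpg,
      cpg_density = n_cpg * 100 / len,
      density_class = as.integer(floor(n_cpg * 100 / len))
    )
}

regions_granges <- function(x, seqlevels = unique(as.character(x$chrom))) {
  # 0-based half-open -> 1-based closed
  GenomicRanges::GRanges(
    factor(as.character(x$chrom), levels = seqlevels),
    IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Associate genes with DMRs through a symmetric flank
#'
#' A gene is associated with a DMR when the DMR, widened by `gene_flank` bp
#' on both sides (clipped at 0), overlaps the gene body by at least one
#' base. The flank is what lets a DMR sitting upstream of a promoter reach
#' its gene; strand is deliberately ignored (the flank is symmetric).
#'
#' @param dmrs Region tibble (`chrom`, `start`, `end`).
#' @param genes Gene tibble (`chrom`, `start`, `end`, `name`), e.g. from
#'   [simulate_genes()] or [read_genes()].
#' @param gene_flank Flank in bp (default 10 kb).
#' @return `dmrs` with `n_genes`, a list-column `genes` of associated gene
#'   names, and `gene_assoc` (comma-separated names, `NA` when none — DMRs
#'   without a gene are retained).
#' @export
associate_genes <- function(dmrs, genes, gene_flank = 1e4) {
  if (nrow(dmrs) == 0) {
    return(mutate(dmrs, n_genes = integer(), genes = list(), gene_assoc = character()))
  }
  flanked <- dmrs
  flanked$start <- pmax(dmrs$start - gene_flank, 0)
  flanked$end <- dmrs$end + gene_flank
  gene_names <- rep(list(character(0)), nrow(dmrs))
  if (nrow(genes) > 0) {
    lv <- union(unique(as.character(dmrs$chrom)), unique(as.character(genes$chrom)))
    hits <- GenomicRanges::findOverlaps(regions_granges(flanked, lv),
                                        regions_granges(genes, lv))
    if (length(hits) > 0) {
      by_q <- split(genes$name[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits))
      gene_names[as.integer(names(by_q))] <- lapply(by_q, unique)
    }
  }
  dmrs |>
    mutate(
      n_genes = vapply(gene_names, length, integer(1)),
      genes = gene_names,
      gene_assoc = vapply(gene_names, function(g) {
        if (length(g) == 0) NA_character_ else paste(g, collapse = ",")
      }, character(1))
    )
}

#' Export annotated DMRs as TSV
#'
#' One row per DMR with name, position, length, number of adjacent core
#' windows, minimum p-value, CpG number, CpG density and gene association.
#'
#' @param dmrs Annotated DMR tibble ([annotate_cpg_density()] +
#'   [associate_genes()]).
#' @param path Output path.
#' @export
write_annotated_dmrs <- function(dmrs, path) {
  keep <- intersect(
    c("dmr_id", "chrom", "start", "end", "length_bp", "max_core_run", "n_core",
      "min_p", "dmr_class", "cpg_count", "cpg_density", "density_class",
      "n_genes", "gene_assoc"),
    names(dmrs)
  )
  write_tsv(dmrs[keep], path)
  invisible(path)
}
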