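# Shared data model (genomes, gene records, mobile elements) and the
# FASTA/GFF3/TSV boundary.  Internally all spans are 0-based half-open;
# GFF3 files are 1-based closed and converted exactly once, here.

#' @keywords internal
empty_genes <- function() {
  data.frame(gene_id = character(0), contig_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             type = character(0), product = character(0),
             protein = character(0), stringsAsFactors = FALSE)
}

#' @keywords internal
empty_spans <- function() {
  data.frame(contig_id = character(0), start = integer(0), end = integer(0),
             class = character(0), stringsAsFactors = FALSE)
}

#' Construct a genome object
#'
#' @param genome_id label for the genome
#' @param contigs named character vector of uppercase nucleotide sequences
#' @param genes data frame with columns gene_id, contig_id, start, end
#'   (0-based half-open), strand, type (CDS/tRNA), product, protein
#' @param element_spans optional data frame of labelled spans
#'   (prophage / IS) with columns contig_id, start, end, class
#' @return an object of class `genome`
#' @export
new_genome <- function(genome_id, contigs = character(0), genes = empty_genes(),
                       element_spans = empty_spans()) {
  g <- structure(list(genome_id = genome_id, contigs = contigs,
                      genes = genes, element_spans = element_spans),
                 class = "genome")
  validate_genome(g)
  g
}

#' @keywords internal
validate_genome <- function(g) {
  if (anyDuplicated(names(g$contigs)))
    stop("duplicate contig ids in genome ", g$genome_id)
  if (nrow(g$genes)) {
    bad <- !(g$genes$contig_id %in% names(g$contigs))
    if (any(bad))
      stop("gene(s) reference unknown contig: ",
           paste(unique(g$genes$contig_id[bad]), collapse = ", "))
    len <- nchar(g$contigs)[g$genes$contig_id]
    if (any(g$genes$start < 0L | g$genes$end > len | g$genes$start >= g$genes$end))
      stop("gene span out of contig bounds in genome ", g$genome_id)
  }
  if (nrow(g$element_spans)) {
    len <- nchar(g$contigs)[g$element_spans$contig_id]
    if (any(is.na(len)) ||
        any(g$element_spans$start < 0L | g$element_spans$end > len))
      stop("element span out of contig bounds in genome ", g$genome_id)
  }
  invisible(g)
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$genome_id, "-", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp,", nrow(x$genes), "gene(s)\n")
  invisible(x)
}

#' Construct a mobile genetic element
#'
#' @param element_id label
#' @param seq nucleotide string
#' @param element_class one of phage, plasmid, chromosome
#' @param genes gene records on the element (coordinates on `seq`)
#' @param owner_genome optional id of the genome that carries the element
#'   (used for self-targeting analysis)
#' @return object of class `mobile_element`
#' @export
new_mobile_element <- function(element_id, seq,
                               element_class = c("phage", "plasmid", "chromosome"),
                               genes = empty_genes(), owner_genome = NA_character_) {
  element_class <- match.arg(element_class)
  structure(list(element_id = element_id, seq = seq,
                 element_class = element_class, genes = genes,
                 owner_genome = owner_genome),
            class = "mobile_element")
}

# translate a CDS span to protein (standard bacterial code; trailing stop
# dropped, internal stops kept as '*')
#' @keywords internal
derive_protein <- function(contig_seq, start, end, strand) {
  dna <- substr(contig_seq, start + 1L, end)
  if (strand == "-") dna <- revcomp(dna)
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return(NA_character_)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(dna, 1L, n)),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Load a genome from FASTA (+ optional GFF3)
#'
#' GFF3 coordinates (1-based closed) are converted to the internal 0-based
#' half-open convention.  Proteins are derived by translating CDS spans with
#' the standard bacterial genetic code unless a `translation` attribute is
#' present.
#'
#' @param fasta_path path to a (multi-)FASTA file
#' @param gff_path optional path to a GFF3 annotation file whose seqids must
#'   match the FASTA record names
#' @param genome_id label; defaults to the FASTA file name without extension
#' @return a [new_genome()] object
#' @export
load_genome <- function(fasta_path, gff_path = NULL, genome_id = NULL) {
  if (is.null(genome_id))
    genome_id <- sub("\\.(fa|fasta|fna)$", "", basename(fasta_path))
  ss <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- toupper(as.character(ss))
  names(contigs) <- sub("\\s.*$", "", names(ss))
  genes <- empty_genes()
  if (!is.null(gff_path)) {
    gr <- rtracklayer::import(gff_path)
    gr <- gr[as.character(gr$type) %in% c("gene", "CDS", "tRNA")]
    if (length(gr)) {
      cid <- as.character(GenomicRanges::seqnames(gr))
      if (!all(cid %in% names(contigs)))
        stop("GFF contig id(s) not present in FASTA: ",
             paste(setdiff(unique(cid), names(contigs)), collapse = ", "))
      ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
        paste0("gene", seq_along(gr))
      prod <- if (!is.null(gr$product)) as.character(gr$product) else
        rep(NA_character_, length(gr))
      genes <- data.frame(
        gene_id = ids, contig_id = cid,
        start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr)),
        type = as.character(gr$type), product = prod,
        protein = NA_character_, stringsAsFactors = FALSE)
      is_cds <- genes$type == "CDS"
      for (i in which(is_cds)) {
        genes$protein[i] <- derive_protein(contigs[[genes$contig_id[i]]],
                                           genes$start[i], genes$end[i],
                                           genes$strand[i])
      }
    }
  }
  new_genome(genome_id, contigs, genes)
}

#' Write a genome to FASTA and GFF3
#'
#' Inverse of [load_genome()]: internal spans are printed back as 1-based
#' closed GFF3 records.
#'
#' @param genome a genome object
#' @param fasta_path output FASTA path
#' @param gff_path optional output GFF3 path (written when the genome has genes)
#' @return invisibly, the genome
#' @export
write_genome <- function(genome, fasta_path, gff_path = NULL) {
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, fasta_path)
  if (!is.null(gff_path)) {
    gn <- genome$genes
    gr <- GenomicRanges::GRanges(
      seqnames = gn$contig_id,
      ranges = IRanges::IRanges(start = gn$start + 1L, end = gn$end),
      strand = gn$strand)
    gr$type <- gn$type
    gr$ID <- gn$gene_id
    gr$product <- gn$product
    suppressWarnings(rtracklayer::export.gff3(gr, gff_path))
  }
  invisible(genome)
}

#' Load a mobile-element pool from FASTA plus a class-metadata TSV
#'
#' @param fasta_path multi-FASTA of element sequences
#' @param meta_path TSV with columns element_id, element_class and optionally
#'   owner_genome
#' @return list of [new_mobile_element()] objects
#' @export
load_elements <- function(fasta_path, meta_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  lapply(seq_along(ss), function(i) {
    m <- meta[meta$element_id == ids[i], , drop = FALSE]
    if (!nrow(m)) stop("element ", ids[i], " missing from metadata")
    new_mobile_element(ids[i], toupper(as.character(ss[[i]])),
                       m$element_class[1],
                       owner_genome = if ("owner_genome" %in% names(m))
                         m$owner_genome[1] else NA_character_)
  })
}

#' @keywords internal
write_elements <- function(elements, fasta_path, meta_path) {
  seqs <- vapply(elements, `[[`, "", "seq")
  names(seqs) <- vapply(elements, `[[`, "", "element_id")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  meta <- data.frame(
    element_id = names(seqs),
    element_class = vapply(elements, `[[`, "", "element_class"),
    owner_genome = vapply(elements, `[[`, "", "owner_genome"),
    stringsAsFactors = FALSE)
  write_tsv(meta, meta_path)
}

# deterministic TSV writer used for all report tables
#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     na = "NA")
}

#' Write the report bundle as TSV tables
#'
#' Emits one row per array / spacer cluster / proto-spacer hit plus the
#' cas, leader, grouping and dating tables.  Output is deterministic:
#' identical inputs give byte-identical files.
#'
#' @param results a report bundle as returned by [run_all()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_tables <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    files <<- c(files, p)
  }
  emit(results$array_table %||% empty_array_table(), "arrays.tsv")
  emit(results$atlas %||% empty_atlas_table(), "spacer_atlas.tsv")
  emit(results$cluster_table %||% empty_cluster_table(), "spacer_clusters.tsv")
  emit(results$hit_table %||% empty_hit_table(), "protospacer_hits.tsv")
  emit(results$cas_table %||% empty_cas_table(), "cas_calls.tsv")
  emit(results$leader_table %||% empty_leader_table(), "leaders.tsv")
  emit(results$anti_table %||% empty_anti_table(), "anti_crispr.tsv")
  emit(results$group_table %||% empty_group_table(), "strain_groups.tsv")
  emit(results$estimate_table %||% empty_estimate_table(), "divergence_estimates.tsv")
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
empty_array_table <- function() {
  data.frame(genome_id = character(0), contig_id = character(0),
             locus = character(0), start = integer(0), end = integer(0),
             n_repeats = integer(0), repeat_len = integer(0),
             consensus = character(0), exact_fraction = numeric(0),
             orientation = character(0), single_repeat = logical(0),
             is_disrupted = logical(0),
             terminal_3prime_degenerate = logical(0),
             stringsAsFactors = FALSE)
}

#' @keywords internal
empty_atlas_table <- function() {
  data.frame(locus = character(0), n_spacers = integer(0),
             n_distinct = integer(0), n_singleton = integer(0),
             singleton_pct = integer(0), n_with_protospacer = integer(0),
             with_protospacer_pct = integer(0), n_protospacers = integer(0),
             n_genic = integer(0), genic_pct = integer(0),
             n_coding_strand = integer(0), coding_strand_pct = integer(0),
             stringsAsFactors = FALSE)
}

#' @keywords internal
empty_cluster_table <- function() {
  data.frame(cluster_id = character(0), representative = character(0),
             locus = character(0), n_occurrences = integer(0),
             n_groups = integer(0), is_singleton = logical(0),
             stringsAsFactors = FALSE)
}

#' @keywords internal
empty_hit_table <- function() {
  data.frame(spacer_id = character(0), genome_id = character(0),
             element_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), mismatches = integer(0),
             identity = numeric(0), context = character(0),
             coding_strand = logical(0), target_class = character(0),
             self_target = logical(0), stringsAsFactors = FALSE)
}

#' @keywords internal
empty_cas_table <- function() {
  data.frame(genome_id = character(0), subtype = character(0),
             gene_name = character(0), status = character(0),
             similarity = numeric(0), evidence = character(0),
             operon_status = character(0), adjacent_locus = character(0),
             stringsAsFactors = FALSE)
}

#' @keywords internal
empty_leader_table <- function() {
  data.frame(genome_id = character(0), locus = character(0),
             side = character(0), start = integer(0), end = integer(0),
             at_fraction = numeric(0), conservation = numeric(0),
             significant = logical(0), stringsAsFactors = FALSE)
}

#' @keywords internal
empty_anti_table <- function() {
  data.frame(genome_id = character(0), locus = character(0),
             matched_cas_genes = character(0), subtype = character(0),
             cognate_subtype_present = logical(0), flagged = logical(0),
             stringsAsFactors = FALSE)
}

#' @keywords internal
empty_group_table <- function() {
  data.frame(genome_id = character(0), group_id = integer(0),
             representative = character(0), stringsAsFactors = FALSE)
}

#' @keywords internal
empty_estimate_table <- function() {
  data.frame(pair = character(0), d = numeric(0), years_clock = numeric(0),
             generations_neutral = numeric(0), years_neutral = numeric(0),
             stringsAsFactors = FALSE)
}
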