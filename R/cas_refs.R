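# Bundled reference Cas protein sets for the two CRISPR/cas subtypes seen in
# Escherichia/Salmonella: the Ecoli subtype (8 co-oriented genes) and the
# Ypest subtype (6 co-oriented genes).  The bundled sequences are SYNTHETIC
# reference proteins generated deterministically: they stand in for curated
# subtype references so the annotation machinery is exercised end-to-end
# without shipping third-party data.  Users can supply their own reference
# FASTA via load_cas_refs().

.ECOLI_GENES <- c("cas2", "cas1", "cse3", "cas5", "cse4", "cse2", "cse1", "cas3")
.YPEST_GENES <- c("cas1", "cas3", "csy1", "csy2", "csy3", "csy4")

.CAS_LEN <- list(
  Ecoli = c(cas2 = 94L, cas1 = 305L, cse3 = 199L, cas5 = 232L, cse4 = 380L,
            cse2 = 160L, cse1 = 502L, cas3 = 888L),
  Ypest = c(cas1 = 324L, cas3 = 700L, csy1 = 441L, csy2 = 337L, csy3 = 342L,
            csy4 = 186L))

#' Canonical gene order of a CRISPR/cas subtype
#'
#' @param subtype "Ecoli" (8 genes) or "Ypest" (6 genes)
#' @return character vector of gene names in operon order
#' @export
cas_subtype_genes <- function(subtype = c("Ecoli", "Ypest")) {
  subtype <- match.arg(subtype)
  if (subtype == "Ecoli") .ECOLI_GENES else .YPEST_GENES
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# lexicographically-first codon per amino acid (deterministic reverse
# translation; translate() of the CDS returns exactly the protein)
#' @keywords internal
codon_for <- function() {
  gc <- Biostrings::GENETIC_CODE
  split_codons <- split(names(gc), unname(gc))
  vapply(split_codons, function(x) sort(x)[1], "")
}

#' @keywords internal
reverse_translate <- function(protein) {
  cf <- codon_for()
  aa <- strsplit(protein, "")[[1]]
  paste0(paste(cf[aa], collapse = ""), "TAA")
}

#' Bundled synthetic Cas reference set
#'
#' Deterministic synthetic reference proteins (and their coding sequences)
#' for one subtype, with realistic lengths per gene.  The same sequences are
#' shipped as FASTA under `inst/extdata/` and used as templates by the
#' synthetic-genome generator.
#'
#' @param subtype "Ecoli" or "Ypest"
#' @return data frame: subtype, gene_name, protein, cds
#' @export
cas_reference_set <- function(subtype = c("Ecoli", "Ypest")) {
  subtype <- match.arg(subtype)
  genes <- cas_subtype_genes(subtype)
  lens <- .CAS_LEN[[subtype]]
  base_seed <- if (subtype == "Ecoli") 90001L else 90101L
  prots <- vapply(seq_along(genes), function(i) {
    with_seed(base_seed + i, paste0(
      "M", paste(sample(.AA20, lens[[genes[i]]] - 1L, replace = TRUE),
                 collapse = "")))
  }, "")
  data.frame(subtype = subtype, gene_name = genes, protein = prots,
             cds = vapply(prots, reverse_translate, "", USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Load Cas reference proteins from FASTA
#'
#' Record names must be `subtype|gene_name` (e.g. `Ecoli|cas3`).  Coding
#' sequences are reconstructed by deterministic reverse translation, which
#' is sufficient for protein-level annotation; for nucleotide-level
#' anti-CRISPR matching supply the generator's own references.
#'
#' @param fasta_path protein FASTA path
#' @return data frame: subtype, gene_name, protein, cds
#' @export
load_cas_refs <- function(fasta_path) {
  ss <- Biostrings::readAAStringSet(fasta_path)
  parts <- strsplit(sub("\\s.*$", "", names(ss)), "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("reference names must be subtype|gene_name")
  prot <- as.character(ss)
  data.frame(subtype = vapply(parts, `[[`, "", 1L),
             gene_name = vapply(parts, `[[`, "", 2L),
             protein = unname(prot),
             cds = vapply(prot, reverse_translate, "", USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Default reference set (both subtypes)
#'
#' @return data frame with Ecoli and Ypest reference rows
#' @export
default_cas_refs <- function() {
  rbind(cas_reference_set("Ecoli"), cas_reference_set("Ypest"))
}

#' @keywords internal
write_cas_ref_fasta <- function(path) {
  refs <- default_cas_refs()
  aa <- Biostrings::AAStringSet(refs$protein)
  names(aa) <- paste0(refs$subtype, "|", refs$gene_name, " synthetic reference")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
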