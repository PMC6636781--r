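#' Construct a bacterial genome
#'
#' Genomes are circular ordered arrays of gene slots. A slot holds one gene,
#' is empty, or is occupied by integrated prophage DNA. Locus arithmetic is
#' modulo the genome length; there is no mutation, so a genome only ever
#' changes through prophage integration or recombination of transduced DNA.
#'
#' @param L genome size in slots.
#' @param gene_tab gene table as returned by [genes()].
#' @param at integer vector of 1-based slots, one per row of `gene_tab`.
#' @return An object of class `bact_genome` with fields `loci` (integer
#'   vector: `0` = empty slot, `k > 0` = row `k` of `genes`, `-j` = slot
#'   occupied by prophage DNA of genotype `j`), `genes` and `prophages`.
#' @examples
#' g <- bacterial_genome(10, genes("resistance", drug = "CAM", active = TRUE,
#'                                 provenance = "A"), at = 6)
#' is_lysogen(g)
#' @export
bacterial_genome <- function(L, gene_tab = NULL, at = NULL) {
  L <- as.integer(L)
  stopifnot(L >= 1L)
  loci <- integer(L)
  if (!is.null(gene_tab)) {
    if (is.null(at)) stop("`at` must give a slot for every gene")
    at <- as.integer(at)
    stopifnot(length(at) == nrow(gene_tab), all(at >= 1L), all(at <= L))
    if (anyDuplicated(at)) stop("two genes assigned to the same slot")
    loci[at] <- seq_len(nrow(gene_tab))
  } else {
    gene_tab <- genes(character(0))
  }
  structure(list(loci = loci,
                 genes = gene_tab,
                 prophages = data.frame(genotype_id = integer(0),
                                        immunity_group = character(0),
                                        start = integer(0), span = integer(0),
                                        stringsAsFactors = FALSE)),
            class = "bact_genome")
}

#' @export
print.bact_genome <- function(x, ...) {
  cat("<bact_genome>", length(x$loci), "slots,", nrow(x$genes), "genes,",
      nrow(x$prophages), "prophage(s)\n")
  act <- active_resistance(x)
  if (length(act)) cat("  active resistance:", paste(act, collapse = ", "), "\n")
  invisible(x)
}

#' Is this genome (or bacterium) a lysogen?
#'
#' Lysogeny is a derived property: a cell is a lysogen if and only if its
#' genome carries at least one integrated prophage.
#'
#' @param x a `bact_genome` or `bacterium`.
#' @return logical scalar.
#' @export
is_lysogen <- function(x) {
  if (inherits(x, "bacterium")) x <- x$genome
  nrow(x$prophages) > 0L
}

#' Drugs a genome confers phenotypic resistance to
#'
#' A genome is phenotypically resistant to a drug if it carries at least one
#' *active* resistance gene for that drug, whether native or transduced; an
#' active transferred copy confers resistance even alongside an inactive
#' native copy.
#'
#' @param x a `bact_genome` or `bacterium`.
#' @return character vector of drug identifiers (possibly empty).
#' @export
active_resistance <- function(x) {
  if (inherits(x, "bacterium")) x <- x$genome
  g <- x$genes
  present <- x$loci[x$loci > 0L]
  g <- g[present, , drop = FALSE]
  unique(g$drug[g$category == "resistance" & g$active %in% TRUE])
}

# number of active resistance genes present in the genome (counts copies)
n_active_resistance <- function(x) {
  if (inherits(x, "bacterium")) x <- x$genome
  g <- x$genes
  present <- x$loci[x$loci > 0L]
  sum(g$category[present] == "resistance" & g$active[present] %in% TRUE)
}

# slots not occupied by prophage DNA, in circular order (values are gene rows
# or 0 for empty slots) -- the substrate for headful packaging
non_prophage_loci <- function(genome) {
  genome$loci[genome$loci >= 0L]
}

# indices of a headful window of `h` consecutive non-prophage slots starting
# at `start` (1-based, circular over the `n_np` non-prophage slots)
headful_window <- function(n_np, start, h) {
  ((start - 1L + seq_len(h) - 1L) %% n_np) + 1L
}

# integrate a prophage at the attB site (genome start); blocked if the genome
# already carries a prophage of the same immunity group
genome_add_prophage <- function(genome, genotype) {
  if (genotype$immunity_group %in% genome$prophages$immunity_group) {
    stop("genome already lysogenic for immunity group ", genotype$immunity_group)
  }
  span <- genotype$prophage_span
  genome$loci <- c(rep.int(-genotype$id, span), genome$loci)
  if (nrow(genome$prophages)) {
    genome$prophages$start <- genome$prophages$start + span
  }
  genome$prophages <- rbind(genome$prophages,
                            data.frame(genotype_id = genotype$id,
                                       immunity_group = genotype$immunity_group,
                                       start = 1L, span = span,
                                       stringsAsFactors = FALSE))
  genome
}

# recombine transduced genes into the genome: cargo rows are appended to the
# gene table and the new slots to the end of the locus array (the designated
# integration region); donor provenance is preserved verbatim
genome_append_genes <- function(genome, cargo) {
  if (nrow(cargo) == 0L) return(genome)
  k <- nrow(genome$genes)
  genome$genes <- rbind(genome$genes, cargo)
  genome$loci <- c(genome$loci, k + seq_len(nrow(cargo)))
  genome
}
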