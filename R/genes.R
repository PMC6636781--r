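#' Construct a table of genes
#'
#' Genes are the atomic unit of the model's explicit genomes. A gene has a
#' functional category (`essential`, `accessory` or `resistance`), and
#' resistance genes additionally carry the antibiotic they act against and an
#' `active` flag: an inactive resistance gene is present in the genome but
#' confers no phenotype (it cannot be activated by mutation in this model;
#' activity can only arrive with a transduced active copy). Every gene keeps a
#' `provenance` tag naming the strain it originated from, preserved verbatim
#' through packaging and recombination so that genome snapshots can colour
#' DNA by origin.
#'
#' @param category character vector in `c("essential", "accessory", "resistance")`.
#' @param drug antibiotic identifier (e.g. `"CAM"`, `"ERM"`); must be set for
#'   resistance genes and `NA` otherwise.
#' @param active logical; phenotype switch, only meaningful for resistance genes.
#' @param provenance strain-of-origin tag.
#' @param label optional human-readable label; autogenerated when `NULL`.
#' @return A `data.frame` with columns `category`, `drug`, `active`,
#'   `provenance`, `label`, one row per gene.
#' @examples
#' genes(c("essential", "resistance"), drug = c(NA, "CAM"),
#'       active = c(NA, TRUE), provenance = "strainA")
#' @export
genes <- function(category, drug = NA_character_, active = NA,
                  provenance = "founder", label = NULL) {
  category <- as.character(category)
  n <- length(category)
  drug <- rep_len(as.character(drug), n)
  active <- rep_len(as.logical(active), n)
  provenance <- rep_len(as.character(provenance), n)
  bad <- !category %in% c("essential", "accessory", "resistance")
  if (any(bad)) {
    stop("unknown gene category: ", paste(unique(category[bad]), collapse = ", "))
  }
  res <- category == "resistance"
  if (any(res & is.na(drug))) {
    stop("resistance genes must name a drug")
  }
  if (any(!res & !is.na(drug))) {
    stop("only resistance genes may carry a drug")
  }
  # activity is undefined for non-resistance genes
  active[!res] <- NA
  active[res & is.na(active)] <- FALSE
  if (is.null(label)) {
    label <- ifelse(res, paste0(drug, "-R"), category)
    label <- paste0(label, "_", seq_len(n))
  }
  data.frame(category = category, drug = drug, active = active,
             provenance = provenance, label = rep_len(label, n),
             stringsAsFactors = FALSE)
}

#' Describe a bacterial strain
#'
#' A strain specification is the synthetic-population recipe used by the
#' scenario initializers: it fixes the genome size, the numbers of essential
#' and accessory genes, the resistance markers (active or inactive), and
#' whether the founders are lysogens. The marker locus defaults to the slot
#' diametrically opposite the prophage integration site, so that a
#' chromosomal marker is maximally distant from the prophage.
#'
#' @param name strain label; also used as the provenance tag of its genes.
#' @param L genome size in gene slots.
#' @param n_essential,n_accessory numbers of essential and accessory genes.
#' @param markers `data.frame` with columns `drug` and `active`, one row per
#'   resistance gene carried by the strain.
#' @param lysogen_of a [phage_genotype()] whose prophage the founders carry,
#'   or `NULL` for non-lysogenic founders.
#' @param marker_locus 1-based slot for the first marker (subsequent markers
#'   occupy the following slots); default `floor(L / 2) + 1`.
#' @return An object of class `strain_spec`.
#' @export
strain_spec <- function(name, L = 100L, n_essential = 20L, n_accessory = 10L,
                        markers = data.frame(drug = "CAM", active = TRUE),
                        lysogen_of = NULL, marker_locus = NULL) {
  L <- as.integer(L)
  stopifnot(L >= 1L, n_essential >= 0L, n_accessory >= 0L)
  if (is.null(marker_locus)) marker_locus <- floor(L / 2) + 1L
  n_genes <- n_essential + n_accessory + nrow(markers)
  if (n_genes > L) stop("genome size L too small for the requested genes")
  if (marker_locus + nrow(markers) - 1L > L) {
    stop("marker_locus places markers beyond the genome end")
  }
  structure(list(name = name, L = L, n_essential = as.integer(n_essential),
                 n_accessory = as.integer(n_accessory), markers = markers,
                 lysogen_of = lysogen_of, marker_locus = as.integer(marker_locus)),
            class = "strain_spec")
}

#' @export
print.strain_spec <- function(x, ...) {
  cat("<strain_spec>", x$name, "\n")
  cat("  L =", x$L, "slots;", x$n_essential, "essential,",
      x$n_accessory, "accessory\n")
  for (i in seq_len(nrow(x$markers))) {
    cat("  marker:", x$markers$drug[i],
        if (isTRUE(x$markers$active[i])) "(active)" else "(inactive)",
        "at locus", x$marker_locus + i - 1L, "\n")
  }
  if (!is.null(x$lysogen_of)) cat("  founders are lysogens\n")
  invisible(x)
}

# gene table for one strain, plus the loci template (0 = empty slot)
strain_gene_layout <- function(spec) {
  gs <- list()
  if (spec$n_essential > 0) {
    gs$ess <- genes(rep("essential", spec$n_essential), provenance = spec$name)
  }
  if (spec$n_accessory > 0) {
    gs$acc <- genes(rep("accessory", spec$n_accessory), provenance = spec$name)
  }
  if (nrow(spec$markers) > 0) {
    gs$res <- genes(rep("resistance", nrow(spec$markers)),
                    drug = spec$markers$drug, active = spec$markers$active,
                    provenance = spec$name)
  }
  tab <- do.call(rbind, gs)
  rownames(tab) <- NULL
  loci <- integer(spec$L)
  k <- 0L
  if (spec$n_essential > 0) {
    loci[seq_len(spec$n_essential)] <- k + seq_len(spec$n_essential)
    k <- k + spec$n_essential
  }
  if (spec$n_accessory > 0) {
    loci[spec$n_essential + seq_len(spec$n_accessory)] <- k + seq_len(spec$n_accessory)
    k <- k + spec$n_accessory
  }
  if (nrow(spec$markers) > 0) {
    loci[spec$marker_locus + seq_len(nrow(spec$markers)) - 1L] <-
      k + seq_len(nrow(spec$markers))
  }
  list(genes = tab, loci = loci)
}
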