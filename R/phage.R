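#' Define a phage genotype
#'
#' A phage genotype fixes the lifestyle (temperate phage can lysogenize,
#' virulent phage only replicate lytically), the probability that a packaged
#' virion is a generalized transducing particle (`p_GT`), the burst size, the
#' headful capacity (in gene slots) of the capsid, the superinfection
#' immunity group, the lysogeny-decision parameters and the induction-curve
#' parameters.
#'
#' The lysogeny decision of a temperate phage saturates with the local
#' free-phage density: an infecting phage lysogenizes with probability
#' `p_lys * n / (n + K_lys)` where `n` counts free virions in the Moore
#' neighbourhood of the infected cell. Prophage induction follows the
#' sigmoid `1 / (1 + alpha * exp(-kappa * stress))`, so `1 / (1 + alpha)` is
#' the spontaneous (zero-stress) induction rate: `alpha = 1e5` corresponds to
#' a spontaneous rate of about `1e-5` per lysogen per iteration, `alpha = 1e3`
#' to about `1e-3`.
#'
#' @param lifestyle `"temperate"` or `"virulent"`.
#' @param p_GT probability in `[0, 1]` that a packaged virion is a
#'   transducing particle.
#' @param burst_size virions released per lysis.
#' @param headful capsid cargo capacity in gene slots.
#' @param immunity_group opaque label; a lysogen is immune to functional
#'   virions of any genotype sharing its prophage's group.
#' @param p_lys maximum lysogenization probability.
#' @param K_lys half-saturation constant (local free-virion count) of the
#'   lysogeny decision.
#' @param alpha,kappa induction-curve parameters (see above).
#' @param prophage_span slots occupied by the integrated prophage.
#' @param id integer genotype identity (used in genome bookkeeping).
#' @return An object of class `phage_genotype`.
#' @examples
#' phi <- phage_genotype("temperate", p_GT = 0.3, burst_size = 50)
#' @export
phage_genotype <- function(lifestyle = c("temperate", "virulent"),
                           p_GT = 0.3, burst_size = 50L, headful = 10L,
                           immunity_group = "A", p_lys = 0.8, K_lys = 2,
                           alpha = 1e5, kappa = 0.4, prophage_span = 10L,
                           id = 1L) {
  lifestyle <- match.arg(lifestyle)
  stopifnot(is.numeric(p_GT), length(p_GT) == 1L, p_GT >= 0, p_GT <= 1,
            burst_size >= 0, headful >= 0,
            p_lys >= 0, p_lys <= 1, K_lys >= 0,
            alpha > 0, kappa > 0, prophage_span >= 1)
  structure(list(lifestyle = lifestyle, p_GT = p_GT,
                 burst_size = as.integer(burst_size),
                 headful = as.integer(headful),
                 immunity_group = as.character(immunity_group),
                 p_lys = p_lys, K_lys = K_lys,
                 alpha = alpha, kappa = kappa,
                 prophage_span = as.integer(prophage_span),
                 id = as.integer(id)),
            class = "phage_genotype")
}

#' @export
print.phage_genotype <- function(x, ...) {
  cat("<phage_genotype>", x$lifestyle,
      sprintf("p_GT=%.3g burst=%d headful=%d group=%s", x$p_GT, x$burst_size,
              x$headful, x$immunity_group), "\n")
  invisible(x)
}

#' Construct a free phage particle
#'
#' A virion either carries phage DNA (a functional particle able to
#' lysogenize or lyse) or a headful of bacterial DNA (a defective
#' generalized transducing particle that can inject its cargo but can never
#' replicate, lyse a cell or lysogenize).
#'
#' @param genotype a [phage_genotype()].
#' @param cargo_kind `"phage_dna"` or `"bacterial_dna"`.
#' @param cargo gene table (as from [genes()]) carried by a transducing
#'   particle; ignored for functional particles. The number of cargo genes
#'   can be at most the genotype's headful capacity (empty slots in the
#'   packaged window take up capacity but carry no gene).
#' @param age iterations since release.
#' @return An object of class `virion`.
#' @export
virion <- function(genotype, cargo_kind = c("phage_dna", "bacterial_dna"),
                   cargo = NULL, age = 0L) {
  cargo_kind <- match.arg(cargo_kind)
  if (cargo_kind == "bacterial_dna") {
    if (is.null(cargo)) cargo <- genes(character(0))
    if (nrow(cargo) > genotype$headful) {
      stop("cargo exceeds the headful capacity of the genotype")
    }
  } else {
    cargo <- NULL
  }
  structure(list(genotype = genotype, cargo_kind = cargo_kind,
                 cargo = cargo, age = as.integer(age)),
            class = "virion")
}

#' @export
print.virion <- function(x, ...) {
  cat("<virion>", x$genotype$lifestyle,
      if (x$cargo_kind == "bacterial_dna") {
        sprintf("transducing particle (%d cargo genes)", nrow(x$cargo))
      } else "functional", "\n")
  invisible(x)
}

#' Construct a bacterium
#'
#' @param genome a [bacterial_genome()].
#' @param strain strain label.
#' @param age iterations lived.
#' @param stress nonnegative antibiotic-exposure signal driving prophage
#'   induction; reset to zero on iterations without exposure.
#' @param exposures consecutive iterations of unprotected antibiotic
#'   exposure accumulated so far (drives delayed lethality).
#' @return An object of class `bacterium`. Lysogen status is always derived
#'   from the genome (see [is_lysogen()]), never stored.
#' @export
bacterium <- function(genome, strain = "strain", age = 0L, stress = 0,
                      exposures = 0L) {
  stopifnot(inherits(genome, "bact_genome"), stress >= 0)
  structure(list(genome = genome, strain = strain, age = as.integer(age),
                 stress = stress, exposures = as.integer(exposures)),
            class = "bacterium")
}

#' @export
print.bacterium <- function(x, ...) {
  cat("<bacterium>", x$strain,
      if (is_lysogen(x)) "(lysogen)" else "",
      "resistant to:", paste(active_resistance(x), collapse = ", "), "\n")
  invisible(x)
}
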