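# The lattice engine: a toroidal W x H grid, each site holding at most one
# bacterium and any number of free virions. Bacteria live in site-indexed
# parallel vectors (occupancy, genome id, strain, age, stress, exposure
# count); free virions in growable parallel vectors (site, genotype, kind,
# cargo reference, age). Each iteration executes, in this fixed order:
#   (1) well-mixed shuffling of all positions
#   (2) antibiotic action (stress + delayed killing)
#   (3) prophage induction (stress-dependent sigmoid) and lysis
#   (4) adsorption: superinfection blocking, transducing injection,
#       lysogeny-vs-lysis decision, burst release
#   (5) free-virion decay
#   (6) intrinsic death
#   (7) roulette-wheel reproduction into free sites
#   (8) time-series recording

# Moore neighbourhood (distance 1, 8 neighbours) index matrix for a toroidal
# W x H lattice; cached per lattice size
moore_neighbors <- function(W, H) {
  key <- paste0(W, "x", H)
  m <- .pt_cache[[key]]
  if (!is.null(m)) return(m)
  idx <- seq_len(W * H) - 1L
  x <- idx %% W
  y <- idx %/% W
  dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  m <- matrix(0L, W * H, 8L)
  for (k in 1:8) {
    m[, k] <- ((x + dx[k]) %% W) + ((y + dy[k]) %% H) * W + 1L
  }
  .pt_cache[[key]] <- m
  m
}

new_state <- function(ctx, cfg) {
  st <- new.env(parent = emptyenv())
  st$ctx <- ctx
  st$cfg <- cfg
  st$W <- cfg$width
  st$H <- cfg$height
  st$n_sites <- cfg$width * cfg$height
  st$nb <- moore_neighbors(cfg$width, cfg$height)
  n <- st$n_sites
  st$occ <- logical(n)
  st$gid <- integer(n)
  st$strain <- integer(n)
  st$age <- integer(n)
  st$stress <- numeric(n)
  st$expo <- integer(n)
  st$vsite <- integer(0)
  st$vgt <- integer(0)
  st$vkind <- integer(0)
  st$vcg <- integer(0)
  st$vcs <- integer(0)
  st$vage <- integer(0)
  st$t <- 0L
  st$cum_trans <- 0L
  st$cum_ind <- 0L
  st$n_blocked <- 0L
  st$n_lost <- 0L
  st$n_lysed <- 0L
  st$n_lysogenized <- 0L
  st$audit_immune_lysed <- 0L
  # virion book-keeping: the free pool changes only by burst (+), adsorption
  # (-) and decay (-); audited in the tests
  st$cum_virions_in <- 0L
  st$cum_adsorbed <- 0L
  st$cum_decayed <- 0L
  st$cum_double_created <- 0L
  st$series <- list()
  st$class_counts <- list()
  class(st) <- "pt_state"
  st
}

place_bacteria <- function(st, n, gid, strain_id) {
  free <- which(!st$occ)
  if (n > length(free)) stop("initial population exceeds free lattice sites")
  sites <- free[sample.int(length(free), n)]
  st$occ[sites] <- TRUE
  st$gid[sites] <- gid
  st$strain[sites] <- strain_id
  st$age[sites] <- 0L
  st$stress[sites] <- 0
  st$expo[sites] <- 0L
  invisible(st)
}

add_virions <- function(st, n, gtid, kind = 0L, cg = 0L, cs = 0L) {
  if (n <= 0L) return(invisible(st))
  vir_append(st, list(site = sample.int(st$n_sites, n, replace = TRUE),
                      gt = rep.int(as.integer(gtid), n),
                      kind = rep.int(as.integer(kind), n),
                      cg = rep.int(as.integer(cg), n),
                      cs = rep.int(as.integer(cs), n)))
}

vir_append <- function(st, nv) {
  k <- length(nv$site)
  if (k == 0L) return(invisible(st))
  st$cum_virions_in <- st$cum_virions_in + k
  st$vsite <- c(st$vsite, nv$site)
  st$vgt <- c(st$vgt, nv$gt)
  st$vkind <- c(st$vkind, nv$kind)
  st$vcg <- c(st$vcg, nv$cg)
  st$vcs <- c(st$vcs, nv$cs)
  st$vage <- c(st$vage, if (is.null(nv$age)) integer(k) else nv$age)
  invisible(st)
}

vir_keep <- function(st, keep) {
  st$vsite <- st$vsite[keep]
  st$vgt <- st$vgt[keep]
  st$vkind <- st$vkind[keep]
  st$vcg <- st$vcg[keep]
  st$vcs <- st$vcs[keep]
  st$vage <- st$vage[keep]
  invisible(st)
}

#' Well-mixed shuffling of all positions
#'
#' The environment is well mixed: every iteration, the bacteria are permuted
#' over the lattice sites (single occupancy preserved) and every free virion
#' is independently reassigned to a uniformly random site. All counts are
#' conserved.
#'
#' @param st a simulation state (internal; exposed for testing and audits).
#' @return the state, invisibly.
#' @keywords internal
#' @export
randomize_positions <- function(st) {
  n <- st$n_sites
  ids <- which(st$occ)
  k <- length(ids)
  if (k) {
    new_sites <- sample.int(n, k)
    occ <- logical(n); gid <- integer(n); strain <- integer(n)
    age <- integer(n); stress <- numeric(n); expo <- integer(n)
    occ[new_sites] <- TRUE
    gid[new_sites] <- st$gid[ids]
    strain[new_sites] <- st$strain[ids]
    age[new_sites] <- st$age[ids]
    stress[new_sites] <- st$stress[ids]
    expo[new_sites] <- st$expo[ids]
    st$occ <- occ; st$gid <- gid; st$strain <- strain
    st$age <- age; st$stress <- stress; st$expo <- expo
  }
  nv <- length(st$vsite)
  if (nv) st$vsite <- sample.int(n, nv, replace = TRUE)
  invisible(st)
}

# drug bitmask applied at iteration `it`
drug_mask_at <- function(st, it) {
  cfg <- st$cfg
  if (is.null(cfg$drugs) || length(cfg$drugs) == 0L || is.na(cfg$drug_start)) {
    return(0L)
  }
  if (it >= cfg$drug_start && it < cfg$drug_start + cfg$drug_duration) {
    Reduce(bitwOr, bitwShiftL(1L, match(cfg$drugs, st$ctx$drugs) - 1L), 0L)
  } else 0L
}

antibiotic_phase <- function(st, mask) {
  cfg <- st$cfg
  r <- st$ctx$reg
  idx <- which(st$occ)
  if (!length(idx)) return(invisible(st))
  if (mask == 0L) {
    st$stress[idx] <- 0
    st$expo[idx] <- 0L
    return(invisible(st))
  }
  protected <- bitwAnd(r$res_mask[st$gid[idx]], mask) == mask
  st$stress[idx] <- cfg$stress_on_exposure
  st$expo[idx[protected]] <- 0L
  un <- idx[!protected]
  if (length(un)) {
    e <- st$expo[un] + 1L
    st$expo[un] <- e
    lethal <- un[e > cfg$drug_delay]
    if (length(lethal)) {
      kill <- lethal[runif(length(lethal)) < cfg$p_kill]
      st$occ[kill] <- FALSE
    }
  }
  invisible(st)
}

# package a burst from each lysing host; returns new-virion vectors
burst_make <- function(st, sites, gts) {
  ctx <- st$ctx
  r <- ctx$reg
  B <- ctx$gt_burst[gts]
  ktr <- rbinom(length(sites), B, ctx$gt_pGT[gts])
  kfu <- B - ktr
  gidh <- st$gid[sites]
  npl <- r$np_len[gidh]
  if (any(ctx$gt_h[gts] > npl)) {
    stop("headful capacity exceeds a host's non-prophage genome size")
  }
  nf <- sum(kfu); nt <- sum(ktr)
  tnpl <- rep.int(npl, ktr)
  tcs <- pmin(floor(runif(nt) * tnpl) + 1L, tnpl)
  list(site = c(rep.int(sites, kfu), rep.int(sites, ktr)),
       gt = c(rep.int(gts, kfu), rep.int(gts, ktr)),
       kind = c(integer(nf), rep.int(1L, nt)),
       cg = c(integer(nf), rep.int(gidh, ktr)),
       cs = c(integer(nf), as.integer(tcs)))
}

induction_phase <- function(st) {
  ctx <- st$ctx
  r <- ctx$reg
  idx <- which(st$occ)
  if (!length(idx)) return(invisible(st))
  lys <- r$is_lys[st$gid[idx]]
  if (!any(lys)) return(invisible(st))
  li <- idx[lys]
  g1 <- r$first_gt[st$gid[li]]
  p <- 1 / (1 + ctx$gt_alpha[g1] * exp(-ctx$gt_kappa[g1] * st$stress[li]))
  ind <- runif(length(li)) < p
  if (!any(ind)) return(invisible(st))
  sites <- li[ind]
  nv <- burst_make(st, sites, g1[ind])
  st$cum_ind <- st$cum_ind + length(sites)
  st$occ[sites] <- FALSE
  vir_append(st, nv)
}

adsorption_phase <- function(st) {
  cfg <- st$cfg
  ctx <- st$ctx
  r <- ctx$reg
  nv <- length(st$vsite)
  if (!nv) return(invisible(st))
  counts <- tabulate(st$vsite, nbins = st$n_sites)
  cand <- which(st$occ[st$vsite])
  ads <- cand[runif(length(cand)) < cfg$p_ads]
  if (!length(ads)) return(invisible(st))
  tr <- ads[st$vkind[ads] == 1L]
  fu <- ads[st$vkind[ads] == 0L]
  newbursts <- NULL

  # transducing injections are processed before any lysis on the same cell:
  # DNA injection is fast relative to the lytic cycle, and transduced DNA
  # can therefore be repackaged by a burst later in the same iteration.
  # Every adsorbed particle recombines (with probability p_recomb); a cell
  # hit by several particles integrates them sequentially in random order,
  # which the registry executes as one coalesced event per cell.
  if (length(tr)) {
    rec <- runif(length(tr)) < cfg$p_recomb
    ord <- tr[rec]
    if (length(ord) > 1L) ord <- ord[sample.int(length(ord))]
    if (length(ord)) {
      sites_all <- st$vsite[ord]
      # stable sort by site keeps the random processing order within a cell
      o2 <- order(sites_all, method = "radix")
      ord <- ord[o2]
      sites_all <- sites_all[o2]
      newcell <- c(TRUE, sites_all[-1L] != sites_all[-length(sites_all)])
      event <- cumsum(newcell)
      sites <- sites_all[newcell]
      old <- st$gid[sites]
      new <- reg_transduce_batch(ctx, old, st$vcg[ord], st$vcs[ord],
                                 ctx$gt_h[st$vgt[ord]], event)
      st$gid[sites] <- new
      st$cum_trans <- st$cum_trans + length(ord)
      nbits <- ctx$nbits
      st$cum_double_created <- st$cum_double_created +
        sum(nbits[r$res_mask[new] + 1L] >= 2L & nbits[r$res_mask[old] + 1L] < 2L)
    }
  }

  if (length(fu)) {
    hostg <- st$gid[st$vsite[fu]]
    bit <- ctx$gt_immbit[st$vgt[fu]]
    blocked <- bitwAnd(r$imm_mask[hostg], bit) > 0L
    st$n_blocked <- st$n_blocked + sum(blocked)
    prod <- fu[!blocked]
    if (length(prod)) {
      # at most one productive functional infection per cell per iteration;
      # the remaining functional virions on that cell are lost
      ordp <- if (length(prod) > 1L) prod[sample.int(length(prod))] else prod
      first <- !duplicated(st$vsite[ordp])
      chosen <- ordp[first]
      st$n_lost <- st$n_lost + sum(!first)
      sites_c <- st$vsite[chosen]
      gtc <- st$vgt[chosen]
      st$audit_immune_lysed <- st$audit_immune_lysed +
        sum(bitwAnd(r$imm_mask[st$gid[sites_c]], ctx$gt_immbit[gtc]) > 0L)
      nbm <- st$nb[sites_c, , drop = FALSE]
      nloc <- .rowSums(counts[nbm], length(sites_c), 8L)
      plys <- ctx$gt_plys[gtc] * nloc / (nloc + ctx$gt_K[gtc])
      plys[ctx$gt_lifestyle[gtc] == 2L] <- 0
      plys[nloc == 0] <- 0
      lysog <- runif(length(chosen)) < plys
      if (any(lysog)) {
        ls <- sites_c[lysog]
        lg <- gtc[lysog]
        for (k in seq_along(ls)) {
          st$gid[ls[k]] <- reg_lysogenize(ctx, st$gid[ls[k]], lg[k])
        }
        st$n_lysogenized <- st$n_lysogenized + length(ls)
      }
      if (any(!lysog)) {
        bs <- sites_c[!lysog]
        newbursts <- burst_make(st, bs, gtc[!lysog])
        st$occ[bs] <- FALSE
        st$n_lysed <- st$n_lysed + length(bs)
      }
    }
  }
  st$cum_adsorbed <- st$cum_adsorbed + length(ads)
  vir_keep(st, -ads)
  if (!is.null(newbursts)) vir_append(st, newbursts)
  invisible(st)
}

decay_phase <- function(st) {
  nv <- length(st$vsite)
  if (!nv) return(invisible(st))
  st$vage <- st$vage + 1L
  # per-virion iid decay executed as count-level binomial thinning
  k <- rbinom(1L, nv, st$cfg$p_decay)
  if (k > 0L) {
    st$cum_decayed <- st$cum_decayed + k
    vir_keep(st, -sample.int(nv, k))
  }
  invisible(st)
}

death_phase <- function(st) {
  cfg <- st$cfg
  idx <- which(st$occ)
  if (!length(idx)) return(invisible(st))
  st$age[idx] <- st$age[idx] + 1L
  die <- runif(length(idx)) < cfg$p_death
  if (is.finite(cfg$max_age)) die <- die | st$age[idx] > cfg$max_age
  st$occ[idx[die]] <- FALSE
  invisible(st)
}

# roulette wheel over each row of a weight matrix via the Gumbel-max trick:
# P(pick column j) = w[i, j] / sum(w[i, ]) for every row i with any mass
roulette_pick <- function(w) {
  g <- -log(-log(runif(length(w))))
  score <- log(w) + g
  dim(score) <- dim(w)
  max.col(score, ties.method = "first")
}

#' Roulette-wheel reproduction into free sites
#'
#' Each free site draws a parent among the living bacteria in its Moore
#' neighbourhood with probability proportional to fitness
#' (`(1 - cost)^k`, `k` = active resistance genes); the offspring is an
#' exact genome copy. Sites without a living neighbour stay empty; a parent
#' may win several sites in one iteration. Parents are the occupants at the
#' start of the phase, so an offspring does not itself reproduce within the
#' iteration of its birth.
#'
#' @param st a simulation state (internal; exposed for testing and audits).
#' @return the state, invisibly.
#' @keywords internal
#' @export
reproduction_step <- function(st) {
  cfg <- st$cfg
  r <- st$ctx$reg
  free <- which(!st$occ)
  if (!length(free)) return(invisible(st))
  oidx <- which(st$occ)
  if (!length(oidx)) return(invisible(st))
  fit_site <- numeric(st$n_sites)
  fit_site[oidx] <- (1 - cfg$cost)^r$n_active[st$gid[oidx]]
  # unprotected antibiotic exposure is bacteriostatic as well as (after the
  # tolerance window) bactericidal: exposed sensitive cells do not divide
  fit_site[st$expo > 0L] <- 0
  nbm <- st$nb[free, , drop = FALSE]
  w <- fit_site[nbm]
  dim(w) <- dim(nbm)
  has <- .rowSums(w, nrow(w), 8L) > 0
  if (!any(has)) return(invisible(st))
  w <- w[has, , drop = FALSE]
  nbm <- nbm[has, , drop = FALSE]
  fsites <- free[has]
  pick <- roulette_pick(w)
  parents <- nbm[cbind(seq_along(fsites), pick)]
  st$occ[fsites] <- TRUE
  st$gid[fsites] <- st$gid[parents]
  st$strain[fsites] <- st$strain[parents]
  st$age[fsites] <- 0L
  st$stress[fsites] <- 0
  st$expo[fsites] <- 0L
  invisible(st)
}

record_phase <- function(st) {
  r <- st$ctx$reg
  oidx <- which(st$occ)
  gidx <- st$gid[oidx]
  nv <- length(st$vsite)
  free_f <- sum(st$vkind == 0L)
  masks <- r$res_mask[gidx]
  st$series[[st$t]] <- c(
    iteration = st$t,
    n_bacteria = length(oidx),
    n_lysogens = sum(r$is_lys[gidx]),
    n_resistant = sum(masks > 0L),
    n_double_resistant = sum(st$ctx$nbits[masks + 1L] >= 2L),
    free_functional = free_f,
    free_transducing = nv - free_f,
    cum_transductions = st$cum_trans,
    cum_inductions = st$cum_ind)
  if (isTRUE(st$cfg$record_classes)) {
    key <- ((st$strain[oidx] - 1L) * st$ctx$n_masks + masks) * 2L +
      r$is_lys[gidx] + 1L
    st$class_counts[[st$t]] <- tabulate(key,
      nbins = length(st$ctx$strains) * st$ctx$n_masks * 2L)
  }
  invisible(st)
}

# one full iteration in the fixed phase order
step_state <- function(st) {
  it <- st$t + 1L
  if (!any(st$occ)) {
    # no bacteria: shuffling, infection and reproduction are no-ops and the
    # free pool only decays
    decay_phase(st)
    st$t <- it
    if (isTRUE(st$cfg$record)) record_phase(st)
    return(invisible(st))
  }
  randomize_positions(st)
  antibiotic_phase(st, drug_mask_at(st, it))
  induction_phase(st)
  adsorption_phase(st)
  decay_phase(st)
  death_phase(st)
  reproduction_step(st)
  st$t <- it
  if (isTRUE(st$cfg$record)) record_phase(st)
  invisible(st)
}

run_state <- function(st, iterations) {
  for (i in seq_len(iterations)) {
    if (!any(st$occ) && length(st$vsite) == 0L) {
      # both populations extinct: later iterations are no-ops
      n_pad <- iterations - i + 1L
      if (isTRUE(st$cfg$record)) {
        for (j in seq_len(n_pad)) {
          st$t <- st$t + 1L
          record_phase(st)
        }
      } else {
        st$t <- st$t + n_pad
      }
      break
    }
    step_state(st)
  }
  invisible(st)
}

outcome_state <- function(st, seed) {
  r <- st$ctx$reg
  alive <- which(st$occ)
  list(bacteria_survived = length(alive) > 0L,
       phage_survived = any(st$vkind == 0L) ||
         (length(alive) > 0L && any(r$is_lys[st$gid[alive]])),
       final_iteration = st$t,
       seed = seed)
}

mask_label <- function(mask, drugs) {
  vapply(mask, function(m) {
    if (m == 0L) return("none")
    paste(drugs[bitwAnd(m, bitwShiftL(1L, seq_along(drugs) - 1L)) > 0L],
          collapse = "+")
  }, character(1))
}

series_df <- function(st) {
  if (!length(st$series)) {
    return(data.frame(iteration = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, st$series))
  rownames(df) <- NULL
  df
}

class_counts_df <- function(st) {
  if (!length(st$class_counts)) return(NULL)
  ctx <- st$ctx
  nm <- ctx$n_masks
  m <- do.call(rbind, st$class_counts)
  keep <- which(colSums(m) > 0L)
  if (!length(keep)) return(NULL)
  k <- keep - 1L
  lys <- k %% 2L == 1L
  mask <- (k %/% 2L) %% nm
  strain <- k %/% (2L * nm) + 1L
  out <- do.call(rbind, lapply(seq_along(keep), function(j) {
    data.frame(iteration = seq_len(nrow(m)),
               strain = ctx$strain_names[strain[j]],
               profile = mask_label(mask[j], ctx$drugs),
               lysogen = lys[j],
               n = m[, keep[j]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run one simulation
#'
#' Builds the initial lattice from the configuration (strains, founder
#' populations, phage inoculum, antibiotic schedule), runs the configured
#' number of iterations and returns the recorded time series and the outcome
#' summary. Deterministic given `(config, seed)`.
#'
#' @param config a configuration from [sim_config()] or [scenario_config()].
#' @param seed integer seed for all randomness of the run.
#' @param keep_state keep the final engine state (for snapshots and audits).
#' @return An object of class `pt_sim`: a list with `series` (per-iteration
#'   counts), `class_counts` (long per-class counts, when recorded),
#'   `outcome` (survival summary) and optionally `state`.
#' @export
run_simulation <- function(config, seed, keep_state = FALSE) {
  validate_config(config)
  set.seed(seed)
  ctx <- new_context(config$strains, config$genotypes,
                     extra_drugs = config$drugs)
  st <- new_state(ctx, config)
  for (p in config$populations) {
    sid <- match(p$strain, ctx$strain_names)
    if (is.na(sid)) stop("unknown strain in populations: ", p$strain)
    place_bacteria(st, p$n, ctx$founders[sid], sid)
  }
  if (!is.null(config$inoculum) && config$inoculum$n > 0L) {
    add_virions(st, config$inoculum$n, config$inoculum$genotype)
  }
  run_state(st, config$iterations)
  structure(list(series = series_df(st),
                 class_counts = class_counts_df(st),
                 outcome = outcome_state(st, seed),
                 config = config,
                 state = if (keep_state) st else NULL),
            class = "pt_sim")
}

#' @export
print.pt_sim <- function(x, ...) {
  o <- x$outcome
  cat("<pt_sim>", o$final_iteration, "iterations; bacteria",
      if (o$bacteria_survived) "survived" else "extinct", "| phage",
      if (o$phage_survived) "survived" else "extinct", "\n")
  invisible(x)
}

#' Run independent replicates of a configuration
#'
#' Replicate seeds are derived deterministically from the master seed, so
#' replicate `k` can be reproduced in isolation. Scenario configurations are
#' dispatched to their dedicated runners (two-phase protocol or
#' gene-shuffling experiment); plain configurations run as single-phase
#' simulations.
#'
#' @param config a [sim_config()] or [scenario_config()].
#' @param n_reps number of replicates.
#' @param master_seed master seed from which replicate seeds are derived.
#' @param record record full per-iteration series for each replicate
#'   (memory-heavier; enables the per-iteration median summary).
#' @return An object of class `pt_replicates`: `outcomes` (one row per
#'   replicate), `survival` (bacteria / phage / joint survival fractions)
#'   and, when `record = TRUE`, `series_median` with the per-iteration
#'   median and 95% interval of the bacterial and free-phage counts.
#' @export
run_replicates <- function(config, n_reps, master_seed, record = FALSE) {
  stopifnot(n_reps >= 1)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  config$record <- record
  config$record_classes <- FALSE
  runner <- scenario_runner(config)
  sims <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    sims[[k]] <- runner(config, seeds[k])
  }
  outcomes <- do.call(rbind, lapply(seq_len(n_reps), function(k) {
    o <- sims[[k]]$outcome
    data.frame(replicate = k, seed = seeds[k],
               bacteria_survived = o$bacteria_survived,
               phage_survived = o$phage_survived,
               joint_survival = o$bacteria_survived && o$phage_survived)
  }))
  survival <- list(bacteria = mean(outcomes$bacteria_survived),
                   phage = mean(outcomes$phage_survived),
                   joint = mean(outcomes$joint_survival))
  series_median <- NULL
  if (record) {
    series_median <- replicate_series_summary(lapply(sims, `[[`, "series"))
  }
  structure(list(outcomes = outcomes, survival = survival,
                 series_median = series_median, config = config),
            class = "pt_replicates")
}

#' @export
print.pt_replicates <- function(x, ...) {
  cat("<pt_replicates>", nrow(x$outcomes), "replicates | survival:",
      sprintf("bacteria %.2f, phage %.2f, joint %.2f",
              x$survival$bacteria, x$survival$phage, x$survival$joint), "\n")
  invisible(x)
}

replicate_series_summary <- function(series_list) {
  cols <- c("n_bacteria", "n_lysogens", "n_double_resistant",
            "free_functional", "free_transducing")
  iters <- max(vapply(series_list, nrow, integer(1)))
  out <- data.frame(iteration = seq_len(iters))
  for (cl in cols) {
    m <- vapply(series_list, function(s) {
      v <- s[[cl]]
      length(v) <- iters
      v[is.na(v)] <- 0
      v
    }, numeric(iters))
    if (is.null(dim(m))) m <- matrix(m, nrow = iters)
    out[[paste0(cl, "_median")]] <- apply(m, 1, median)
    out[[paste0(cl, "_lo")]] <- apply(m, 1, quantile, probs = 0.025, names = FALSE)
    out[[paste0(cl, "_hi")]] <- apply(m, 1, quantile, probs = 0.975, names = FALSE)
  }
  out
}
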