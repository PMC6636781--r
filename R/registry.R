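# Internal population context and genome registry.
#
# The engine stores each distinct genome exactly once in a registry and lets
# bacteria reference genomes by integer id: reproduction copies an id,
# while the only two genome-modifying events (prophage integration and
# recombination of transduced cargo) create new registry entries.
#
# The registry is laid out for speed under heavy transduction loads:
# * the packaging substrate (the circular sequence of non-prophage slots) of
#   every genome lives in one concatenated integer buffer `np_all`,
#   addressed by per-genome offset and length, so headful windows for a
#   whole batch of transductions are gathered with a handful of vectorized
#   operations and no per-event allocation;
# * a transduction entry is just four integers (parent genome, donor
#   genome, window start, headful size) next to the incrementally updated
#   per-genome metadata (genome length, substrate length, number of active
#   resistance genes, bitmask of drugs with active resistance, bitmask of
#   prophage immunity groups, lysogeny flag, induction genotype);
# * founder and prophage-integration entries additionally keep a small
#   record (locus array, prophage annotation) in a hash environment; the
#   full locus array of a transduced genome is only reconstructed -- by
#   replaying its event chain -- when a genome snapshot asks for it.

new_context <- function(strains, genotypes, extra_drugs = character(0)) {
  ctx <- new.env(parent = emptyenv())
  if (inherits(strains, "strain_spec")) strains <- list(strains)
  if (inherits(genotypes, "phage_genotype")) genotypes <- list(genotypes)

  # genotype attribute vectors, indexed by genotype id
  ids <- vapply(genotypes, `[[`, integer(1), "id")
  if (length(ids) && !identical(sort(ids), seq_along(ids))) {
    stop("phage genotype ids must be 1..n")
  }
  genotypes <- genotypes[order(ids)]
  ctx$genotypes <- genotypes
  ctx$gt_lifestyle <- vapply(genotypes, function(g) {
    if (g$lifestyle == "temperate") 1L else 2L
  }, integer(1))
  ctx$gt_pGT <- vapply(genotypes, `[[`, numeric(1), "p_GT")
  ctx$gt_burst <- vapply(genotypes, `[[`, integer(1), "burst_size")
  ctx$gt_h <- vapply(genotypes, `[[`, integer(1), "headful")
  ctx$gt_plys <- vapply(genotypes, `[[`, numeric(1), "p_lys")
  ctx$gt_K <- vapply(genotypes, `[[`, numeric(1), "K_lys")
  ctx$gt_alpha <- vapply(genotypes, `[[`, numeric(1), "alpha")
  ctx$gt_kappa <- vapply(genotypes, `[[`, numeric(1), "kappa")
  ctx$gt_span <- vapply(genotypes, `[[`, integer(1), "prophage_span")
  groups <- unique(vapply(genotypes, `[[`, character(1), "immunity_group"))
  ctx$imm_groups <- groups
  ctx$gt_immbit <- vapply(genotypes, function(g) {
    bitwShiftL(1L, match(g$immunity_group, groups) - 1L)
  }, integer(1))

  # global gene table across strains
  ctx$strains <- strains
  ctx$strain_names <- vapply(strains, `[[`, character(1), "name")
  layouts <- lapply(strains, strain_gene_layout)
  tabs <- lapply(layouts, `[[`, "genes")
  ctx$genes <- do.call(rbind, tabs)
  rownames(ctx$genes) <- NULL
  drugs <- unique(c(stats::na.omit(ctx$genes$drug), extra_drugs))
  if (length(drugs) > 30L) stop("too many distinct drugs")
  ctx$drugs <- drugs
  act <- ctx$genes$category == "resistance" & ctx$genes$active %in% TRUE
  ctx$g_act <- act
  ctx$g_bit <- ifelse(act, bitwShiftL(1L, match(ctx$genes$drug, drugs) - 1L), 0L)
  ctx$g_bit[is.na(ctx$g_bit)] <- 0L
  # resistance-profile bookkeeping: number of set drug bits per mask value
  ctx$n_masks <- bitwShiftL(1L, length(drugs))
  ctx$nbits <- vapply(0:(ctx$n_masks - 1L), function(m) {
    sum(bitwAnd(m, bitwShiftL(1L, 0:29)) > 0L)
  }, integer(1))

  ctx$reg <- reg_new()

  # founder genome per strain (with prophage when the strain is a lysogen)
  offset <- 0L
  ctx$founders <- integer(length(strains))
  for (i in seq_along(strains)) {
    loci <- layouts[[i]]$loci
    loci[loci > 0L] <- loci[loci > 0L] + offset
    offset <- offset + nrow(tabs[[i]])
    gid <- reg_add(ctx, loci)
    pro <- strains[[i]]$lysogen_of
    if (!is.null(pro)) gid <- reg_lysogenize(ctx, gid, pro$id)
    ctx$founders[i] <- gid
  }
  names(ctx$founders) <- ctx$strain_names
  ctx
}

reg_new <- function(cap = 1024L) {
  r <- new.env(parent = emptyenv())
  r$n <- 0L
  r$cap <- cap
  # concatenated packaging substrates
  r$np_all <- integer(16384L)
  r$np_cap <- 16384L
  r$np_used <- 0L
  # per-genome metadata
  r$len <- integer(cap)
  r$np_len <- integer(cap)
  r$np_off <- integer(cap)
  r$n_active <- integer(cap)
  r$res_mask <- integer(cap)
  r$imm_mask <- integer(cap)
  r$is_lys <- logical(cap)
  r$first_gt <- integer(cap)
  # transduction lineage (0 = not a transduction entry)
  r$parent <- integer(cap)
  r$donor <- integer(cap)
  r$cstart <- integer(cap)
  r$ch <- integer(cap)
  # founder / prophage-integration records (locus array, prophage runs)
  r$records <- new.env(parent = emptyenv(), hash = TRUE, size = 1024L)
  r$keys <- new.env(parent = emptyenv(), hash = TRUE, size = 8192L)
  r
}

int_fields <- c("len", "np_len", "np_off", "n_active", "res_mask", "imm_mask",
                "first_gt", "parent", "donor", "cstart", "ch")

reg_grow <- function(r, need = 1L) {
  cap2 <- r$cap
  while (cap2 < r$n + need) cap2 <- cap2 * 2L
  for (f in int_fields) {
    v <- r[[f]]
    r[[f]] <- NULL
    length(v) <- cap2
    v[is.na(v)] <- 0L
    r[[f]] <- v
  }
  v <- r$is_lys
  r$is_lys <- NULL
  length(v) <- cap2
  v[is.na(v)] <- FALSE
  r$is_lys <- v
  r$cap <- cap2
  invisible(r)
}

# reserve space in the substrate buffer and return the 0-based offset
np_reserve <- function(r, k) {
  if (r$np_used + k > r$np_cap) {
    cap2 <- r$np_cap
    while (cap2 < r$np_used + k) cap2 <- cap2 * 2L
    v <- r$np_all
    r$np_all <- NULL
    length(v) <- cap2
    r$np_all <- v
    r$np_cap <- cap2
  }
  off <- r$np_used
  r$np_used <- r$np_used + k
  off
}

# packaging substrate of genome `gid` (gene rows / 0 for empty slots, in
# circular order). Substrates of transduced genomes are materialised lazily:
# an entry is only written to the buffer when the genome actually donates
# DNA (its transducing particle injects) or is asked for directly.
reg_np <- function(r, gid) {
  if (r$np_off[gid] < 0L) reg_np_materialize(r, gid)
  r$np_all[(r$np_off[gid] + 1L):(r$np_off[gid] + r$np_len[gid])]
}

reg_np_materialize <- function(r, gid) {
  if (r$np_off[gid] >= 0L) return(invisible(r))
  rec <- get0(as.character(gid), envir = r$records, inherits = FALSE)
  if (!is.null(rec) && !is.null(rec$lys_parent)) {
    # prophage integration shares the parent's substrate
    reg_np_materialize(r, rec$lys_parent)
    v <- r$np_off; r$np_off <- NULL; v[gid] <- v[rec$lys_parent]; r$np_off <- v
    return(invisible(r))
  }
  p <- r$parent[gid]
  reg_np_materialize(r, p)
  cargo <- if (!is.null(rec)) {
    rec$cargo  # coalesced multi-window event: cargo recorded explicitly
  } else {
    d <- r$donor[gid]
    reg_np_materialize(r, d)
    h <- r$ch[gid]
    r$np_all[r$np_off[d] +
               ((r$cstart[gid] - 1L + 0:(h - 1L)) %% r$np_len[d]) + 1L]
  }
  pl <- r$np_len[p]
  off <- np_reserve(r, pl + length(cargo))
  v <- r$np_all
  r$np_all <- NULL
  v[off + seq_len(pl)] <- v[r$np_off[p] + seq_len(pl)]
  v[off + pl + seq_along(cargo)] <- cargo
  r$np_all <- v
  v <- r$np_off; r$np_off <- NULL; v[gid] <- off; r$np_off <- v
  invisible(r)
}

# splice one set of metadata values at index i (detach-modify-reattach keeps
# the vectors reference-count 1 so the writes are in place)
reg_write_meta <- function(r, i, len, np_len, np_off, n_active, res_mask,
                           imm_mask, is_lys, first_gt, parent = 0L,
                           donor = 0L, cstart = 0L, ch = 0L) {
  vals <- list(len = len, np_len = np_len, np_off = np_off,
               n_active = n_active, res_mask = res_mask, imm_mask = imm_mask,
               first_gt = first_gt, parent = parent, donor = donor,
               cstart = cstart, ch = ch)
  for (f in int_fields) {
    v <- r[[f]]
    r[[f]] <- NULL
    v[i] <- vals[[f]]
    r[[f]] <- v
  }
  v <- r$is_lys; r$is_lys <- NULL; v[i] <- is_lys; r$is_lys <- v
  invisible(r)
}

# add a founder genome with an explicit locus array
reg_add <- function(ctx, loci, pro_gt = integer(0), pro_start = integer(0),
                    pro_span = integer(0)) {
  r <- ctx$reg
  if (r$n + 1L > r$cap) reg_grow(r)
  i <- r$n + 1L
  np <- loci[loci >= 0L]
  present <- np[np > 0L]
  off <- np_reserve(r, length(np))
  v <- r$np_all; r$np_all <- NULL; v[off + seq_along(np)] <- np; r$np_all <- v
  reg_write_meta(r, i,
                 len = length(loci), np_len = length(np), np_off = off,
                 n_active = sum(ctx$g_act[present]),
                 res_mask = Reduce(bitwOr, ctx$g_bit[present], 0L),
                 imm_mask = Reduce(bitwOr, ctx$gt_immbit[pro_gt], 0L),
                 is_lys = length(pro_gt) > 0L,
                 first_gt = if (length(pro_gt)) pro_gt[1L] else 0L)
  assign(as.character(i),
         list(loci = loci, pro_gt = pro_gt, pro_start = pro_start,
              pro_span = pro_span),
         envir = r$records)
  r$n <- i
  i
}

# integrate a prophage of genotype `gtid` into genome `gid` (memoised); the
# prophage inserts at the attB site at the genome start, so a marker at slot
# L/2 + 1 sits maximally distant from the integration site. Prophage DNA is
# not packaging substrate, so the substrate is shared with the parent.
reg_lysogenize <- function(ctx, gid, gtid) {
  r <- ctx$reg
  key <- paste0("L", gid, ".", gtid)
  hit <- r$keys[[key]]
  if (!is.null(hit)) return(hit)
  if (r$n + 1L > r$cap) reg_grow(r)
  span <- ctx$gt_span[gtid]
  pro <- reg_pro(r, gid)
  i <- r$n + 1L
  reg_write_meta(r, i,
                 len = r$len[gid] + span,
                 np_len = r$np_len[gid], np_off = r$np_off[gid],
                 n_active = r$n_active[gid],
                 res_mask = r$res_mask[gid],
                 imm_mask = bitwOr(r$imm_mask[gid], ctx$gt_immbit[gtid]),
                 is_lys = TRUE,
                 first_gt = if (r$first_gt[gid] > 0L) r$first_gt[gid] else gtid,
                 parent = gid)
  assign(as.character(i),
         list(lys_parent = gid, gtid = gtid, span = span,
              pro_gt = c(pro$pro_gt, gtid),
              pro_start = c(pro$pro_start + span, 1L),
              pro_span = c(pro$pro_span, span)),
         envir = r$records)
  r$n <- i
  assign(key, i, envir = r$keys)
  i
}

# the gene slots packaged by a headful window on genome `donor`
reg_cargo <- function(ctx, donor, start, h) {
  r <- ctx$reg
  if (r$np_off[donor] < 0L) reg_np_materialize(r, donor)
  n_np <- r$np_len[donor]
  idx <- r$np_off[donor] + ((start - 1L + 0:(h - 1L)) %% n_np) + 1L
  r$np_all[idx]
}

# recombine one transduced headful into genome `gid`
reg_transduce <- function(ctx, gid, donor, start, h) {
  reg_transduce_batch(ctx, gid, donor, start, h, seq_along(gid))[1L]
}

# batched transduction. One *event* integrates everything a recipient cell
# received this iteration; an event may span several headful windows
# (sequential integration at the integration region == concatenation of the
# windows in processing order). Inputs are parallel per-window vectors
# (`donors`, `starts`, `hs`) plus `event`, a nondecreasing event index per
# window mapping it to its recipient in `gids` (one entry per event). The
# whole batch is executed with vectorized gathers on the substrate buffer.
reg_transduce_batch <- function(ctx, gids, donors, starts, hs, event) {
  r <- ctx$reg
  k <- length(gids)
  if (k == 0L) return(integer(0))
  for (d in unique(donors)) {
    if (r$np_off[d] < 0L) reg_np_materialize(r, d)
  }
  # gather every cargo window from the concatenated substrate buffer
  slot_ev <- rep.int(event, hs)
  tpos <- sequence(hs) - 1L
  n_np_w <- rep.int(r$np_len[donors], hs)
  idx <- rep.int(r$np_off[donors], hs) +
    ((rep.int(starts - 1L, hs) + tpos) %% n_np_w) + 1L
  w <- r$np_all[idx]
  # per-event metadata deltas (the +1 padding maps empty slots to index 1)
  gact1 <- c(FALSE, ctx$g_act)
  gbit1 <- c(0L, ctx$g_bit)
  n_active_d <- as.integer(rowsum_int(gact1[w + 1L] + 0L, slot_ev, k))
  mask_d <- integer(k)
  gb <- gbit1[w + 1L]
  for (bit in unique(ctx$g_bit[ctx$g_bit > 0L])) {
    mask_d <- bitwOr(mask_d,
                     bit * (rowsum_int((gb == bit) + 0L, slot_ev, k) > 0L))
  }
  # the new substrates (parent substrate + cargo) are materialised lazily
  th <- as.integer(rowsum_int(hs, event, k))
  newlen <- r$np_len[gids] + th
  # metadata splice; lysogeny status is inherited unchanged
  if (r$n + k > r$cap) reg_grow(r, k)
  new <- r$n + seq_len(k)
  il <- r$is_lys[gids]
  single <- tabulate(event, k) == 1L
  first_w <- match(seq_len(k), event)
  vals <- list(len = r$len[gids] + th, np_len = newlen,
               np_off = rep.int(-1L, k),
               n_active = r$n_active[gids] + n_active_d,
               res_mask = bitwOr(r$res_mask[gids], mask_d),
               imm_mask = r$imm_mask[gids],
               first_gt = r$first_gt[gids],
               parent = gids,
               donor = ifelse(single, donors[first_w], 0L),
               cstart = ifelse(single, starts[first_w], 0L),
               ch = ifelse(single, hs[first_w], 0L))
  for (f in int_fields) {
    vv <- r[[f]]
    r[[f]] <- NULL
    vv[new] <- vals[[f]]
    r[[f]] <- vv
  }
  vv <- r$is_lys; r$is_lys <- NULL; vv[new] <- il; r$is_lys <- vv
  r$n <- r$n + k
  # multi-window events keep an explicit cargo record for lineage replay
  if (any(!single)) {
    ends <- cumsum(th)
    starts_c <- ends - th + 1L
    for (j in which(!single)) {
      assign(as.character(new[j]),
             list(tr_parent = gids[j],
                  cargo = w[seq.int(starts_c[j], ends[j])]),
             envir = r$records)
    }
  }
  new
}

# integer rowsum over groups 1..k (positions absent from `g` count zero)
rowsum_int <- function(x, g, k) {
  out <- numeric(k)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# full locus array of `gid` (0 empty, >0 gene row, -j prophage DNA of
# genotype j), reconstructed by replaying the event chain
reg_loci <- function(r, gid) {
  rec <- get0(as.character(gid), envir = r$records, inherits = FALSE)
  if (!is.null(rec)) {
    if (!is.null(rec$loci)) return(rec$loci)
    loci <- if (!is.null(rec$tr_parent)) {
      # coalesced transduction: parent loci plus the recorded cargo
      c(reg_loci(r, rec$tr_parent), rec$cargo)
    } else {
      # prophage integration: prepend the prophage slots
      c(rep.int(-rec$gtid, rec$span), reg_loci(r, rec$lys_parent))
    }
    rec$loci <- loci
    assign(as.character(gid), rec, envir = r$records)
    return(loci)
  }
  # transduction entry: parent loci plus the cargo window of the donor
  d <- r$donor[gid]
  if (r$np_off[d] < 0L) reg_np_materialize(r, d)
  cargo <- r$np_all[(r$np_off[d] +
                       ((r$cstart[gid] - 1L + 0:(r$ch[gid] - 1L)) %%
                          r$np_len[d])) + 1L]
  c(reg_loci(r, r$parent[gid]), cargo)
}

# prophage annotation (genotype ids, starts, spans): transduction records
# inherit it from the nearest ancestor that carries it
reg_pro <- function(r, gid) {
  repeat {
    rec <- get0(as.character(gid), envir = r$records, inherits = FALSE)
    if (!is.null(rec) && !is.null(rec$pro_gt)) {
      return(list(pro_gt = rec$pro_gt, pro_start = rec$pro_start,
                  pro_span = rec$pro_span))
    }
    gid <- r$parent[gid]
  }
}
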