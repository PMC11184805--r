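#' Specification for the MSAP band simulator
#'
#' Describes a synthetic MSAP cohort: two parent groups and the hybrid, each
#' with replicate individuals typed at `n_sites` CCGG loci, with planted
#' per-group methylation levels and planted parent-to-hybrid methylation
#' events.
#'
#' @param n_sites number of CCGG loci.
#' @param group_meth_levels named numeric vector (`MH`, `MA`, `F4`) of target
#'   per-individual methylation levels, fractions in `[0, 1]`.
#' @param n_demeth_sites number of planted demethylation events (polymorphic
#'   in the parents, monomorphic in the hybrid).
#' @param n_hyper_sites number of planted hypermethylation events
#'   (polymorphic only in the hybrid).
#' @param replicates_per_group biological replicates per group.
#' @param noise_rate per-band flip probability applied after state
#'   assignment. Defaults to 0 (no replicate-to-replicate band noise).
#' @param primer_counts named integer vector of sites per selective primer
#'   pair; must sum to `n_sites`. Site ids are `<primer>_<fragment size>`.
#' @param seed integer seed.
#' @return An object of class `msap_sim_spec`.
#' @export
msap_sim_spec <- function(n_sites = 740,
                          group_meth_levels = c(MH = 0.856, MA = 0.824,
                                                F4 = 0.745),
                          n_demeth_sites = 50, n_hyper_sites = 26,
                          replicates_per_group = 4, noise_rate = 0,
                          primer_counts = NULL, seed = 1L) {
  n_sites <- check_count(n_sites, "n_sites", positive = TRUE)
  if (!all(GROUPS %in% names(group_meth_levels)))
    stopf("group_meth_levels must name all of {%s}",
          paste(GROUPS, collapse = ", "))
  check_fraction(group_meth_levels, "group_meth_levels")
  check_fraction(noise_rate, "noise_rate")
  n_demeth_sites <- check_count(n_demeth_sites, "n_demeth_sites")
  n_hyper_sites <- check_count(n_hyper_sites, "n_hyper_sites")
  if (n_demeth_sites + n_hyper_sites > n_sites)
    stopf("planted event counts exceed n_sites")
  replicates_per_group <- check_count(replicates_per_group,
                                      "replicates_per_group", positive = TRUE)
  if (is.null(primer_counts)) {
    base <- c("E-ACA/HM-TCAA" = 265, "E-ACT/HM-TCAA" = 200,
              "E-ACC/HM-TCAA" = 275)
    primer_counts <- floor(base / 740 * n_sites)
    primer_counts[1L] <- primer_counts[1L] + n_sites - sum(primer_counts)
  }
  if (sum(primer_counts) != n_sites)
    stopf("primer_counts must sum to n_sites")
  structure(list(n_sites = n_sites,
                 group_meth_levels = group_meth_levels[GROUPS],
                 n_demeth_sites = n_demeth_sites,
                 n_hyper_sites = n_hyper_sites,
                 replicates_per_group = replicates_per_group,
                 noise_rate = noise_rate, primer_counts = primer_counts,
                 seed = as.integer(seed)),
            class = "msap_sim_spec")
}

#' Simulate an MSAP cohort with planted methylation truth
#'
#' Builds a per-group consensus methylation pattern that realises the target
#' methylation levels and the planted event counts exactly, then emits
#' replicate individuals (identical to the consensus, optionally corrupted by
#' symmetric per-band flips).
#'
#' The level of an individual is polymorphic bands over banded loci, so the
#' generator has two degrees of freedom per group: which sites are
#' polymorphic, and which sites are fully methylated (bandless, dropping out
#' of the denominator). Planted demethylation sites are polymorphic in both
#' parents and unmethylated in the hybrid; hypermethylation sites are
#' unmethylated in the parents and polymorphic in the hybrid. All remaining
#' polymorphic sites are shared by the hybrid and at least one parent, so no
#' spurious events exist at noise 0. Parents, being more methylated, absorb
#' any surplus methylation as fully-methylated uninformative sites, which is
#' what reconciles level targets with small event counts.
#'
#' @param spec an [msap_sim_spec()].
#' @return List with `profiles` (list of [msap_profile()]; replicates named
#'   `<group>_<i>`) and `truth` (list: `events` data.frame, `levels` realized
#'   per-group levels at noise 0, `consensus` per-group site pattern matrix
#'   with entries `POLY`/`BAND`/`NONE`).
#' @export
simulate_msap <- function(spec) {
  stopifnot(inherits(spec, "msap_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_sites
    L <- spec$group_meth_levels
    nd <- spec$n_demeth_sites
    nh <- spec$n_hyper_sites

    sizes <- unlist(lapply(spec$primer_counts, function(k) seq_len(k) + 49L))
    site_ids <- paste0(rep(names(spec$primer_counts), spec$primer_counts),
                       "_", sizes)

    p_f4 <- round(L[["F4"]] * n)
    if (p_f4 < nh)
      stopf("F4 methylation level too low to host %d hypermethylation sites",
            nh)
    if (p_f4 - nh + nd > n - nh)
      stopf("planted configuration needs more than n_sites loci")

    idx <- sample.int(n)                       # random site layout
    hyper <- idx[seq_len(nh)]
    demeth <- idx[nh + seq_len(nd)]
    shared <- idx[nh + nd + seq_len(p_f4 - nh)] # poly in F4 and parents
    rest <- setdiff(idx, c(hyper, demeth, shared))

    # polymorphic site sets per group
    poly <- list(F4 = c(shared, hyper))
    u_set <- list(F4 = integer(0))
    dropped <- integer(0)  # shared sites already dropped by the other parent
    for (g in c("MH", "MA")) {
      pg <- c(shared, demeth)
      cap <- round(L[[g]] * n)
      if (length(pg) > cap) {
        drop_n <- length(pg) - cap
        # a shared site must stay polymorphic in at least one parent,
        # otherwise it would read as a spurious hypermethylation event
        droppable <- setdiff(shared, dropped)
        if (length(droppable) < drop_n)
          stopf("cannot realise level %.3f for group %s with planted events",
                L[[g]], g)
        drop_g <- droppable[sample.int(length(droppable), drop_n)]
        dropped <- c(dropped, drop_g)
        pg <- setdiff(pg, drop_g)
      }
      n_inf <- round(length(pg) / max(L[[g]], 1e-12))
      n_uninf <- max(0L, n - n_inf)
      if (n_uninf > length(rest))
        stopf("not enough free sites to place uninformative loci for %s", g)
      poly[[g]] <- pg
      u_set[[g]] <- if (n_uninf > 0L)
        rest[sample.int(length(rest), n_uninf)] else integer(0)
    }

    consensus <- sapply(GROUPS, function(g) {
      v <- rep("BAND", n)
      v[poly[[g]]] <- "POLY"
      v[u_set[[g]]] <- "NONE"
      v
    })
    rownames(consensus) <- site_ids

    # sub-state of polymorphic sites: internal (msp only) or hemi (hpa only)
    profiles <- list()
    for (g in GROUPS) {
      internal <- stats::runif(n) < 0.5   # per (group, site)
      hpa0 <- ifelse(consensus[, g] == "BAND", 1L,
              ifelse(consensus[, g] == "NONE", 0L,
                     ifelse(internal, 0L, 1L)))
      msp0 <- ifelse(consensus[, g] == "BAND", 1L,
              ifelse(consensus[, g] == "NONE", 0L,
                     ifelse(internal, 1L, 0L)))
      for (r in seq_len(spec$replicates_per_group)) {
        hpa <- hpa0; msp <- msp0
        if (spec$noise_rate > 0) {
          fh <- stats::runif(n) < spec$noise_rate
          fm <- stats::runif(n) < spec$noise_rate
          hpa <- ifelse(fh, 1L - hpa, hpa)
          msp <- ifelse(fm, 1L - msp, msp)
        }
        id <- paste0(g, "_", r)
        profiles[[id]] <- msap_profile(id, g, site_ids, hpa, msp)
      }
    }

    events <- data.frame(
      site_id = site_ids[c(demeth, hyper)],
      event_type = rep(c("DEMETHYLATION", "HYPERMETHYLATION"), c(nd, nh)),
      stringsAsFactors = FALSE)
    realized <- vapply(GROUPS, function(g)
      length(poly[[g]]) / (n - length(u_set[[g]])), numeric(1))
    list(profiles = profiles,
         truth = list(events = events, levels = realized,
                      consensus = consensus))
  })
}

#' Write simulated MSAP band matrices as per-individual CSV files
#'
#' Emits `bands_<individual>_<enzyme>.csv` files (header `site_id,present`)
#' in the GeneMapper-export dialect read by [read_msap_bands()].
#'
#' @param profiles list of [msap_profile()] objects.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_msap_bands <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (p in profiles) {
    for (enz in c("HpaII", "MspI")) {
      path <- file.path(dir, sprintf("bands_%s_%s.csv", p$individual_id, enz))
      utils::write.csv(data.frame(site_id = p$site_ids,
                                  present = if (enz == "HpaII") p$hpa
                                            else p$msp),
                       path, row.names = FALSE, quote = FALSE)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Tally MSAP sites per selective primer pair
#'
#' @param site_ids character vector of site ids of the form
#'   `<primer>_<fragment size>`.
#' @return List with `per_primer` (named counts) and `total`.
#' @export
site_counts_by_primer <- function(site_ids) {
  primer <- sub("_[^_]*$", "", site_ids)
  tab <- table(primer)
  list(per_primer = stats::setNames(as.integer(tab), names(tab)),
       total = length(site_ids))
}
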