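#' Paired MSAP band profile for one individual
#'
#' Bundles the HpaII and MspI presence/absence vectors of a single plant over
#' a shared index of CCGG loci. MSAP scores methylation by digesting the same
#' DNA with the isoschizomers HpaII and MspI, which recognise CCGG but differ
#' in methylation sensitivity, so presence/absence differences between the
#' two band patterns encode the methylation state of each site.
#'
#' @param individual_id character scalar identifying the plant.
#' @param group group label, one of `"MH"`, `"MA"`, `"F4"`.
#' @param site_ids character vector of CCGG locus identifiers
#'   (conventionally `<primer pair>_<fragment size>`).
#' @param hpa,msp binary (0/1) vectors: band present in the HpaII / MspI
#'   pattern, same length and order as `site_ids`.
#' @return An object of class `msap_profile`.
#' @examples
#' p <- msap_profile("MH_1", "MH", c("s1", "s2"), hpa = c(1, 0), msp = c(1, 1))
#' classify_site_states(p)
#' @export
msap_profile <- function(individual_id, group, site_ids, hpa, msp) {
  check_group(group)
  hpa <- as.integer(hpa); msp <- as.integer(msp)
  n <- length(site_ids)
  if (length(hpa) != n || length(msp) != n)
    stopf("site_ids, hpa and msp must have equal length")
  if (anyNA(hpa) || anyNA(msp) || !all(hpa %in% 0:1) || !all(msp %in% 0:1))
    stopf("band vectors must be binary (0/1)")
  if (anyDuplicated(site_ids))
    stopf("duplicated site_ids in profile '%s'", individual_id)
  structure(list(individual_id = as.character(individual_id),
                 group = group, site_ids = as.character(site_ids),
                 hpa = hpa, msp = msp),
            class = "msap_profile")
}

#' @export
print.msap_profile <- function(x, ...) {
  cat(sprintf("MSAP profile '%s' (group %s): %d CCGG sites, %d polymorphic\n",
              x$individual_id, x$group, length(x$site_ids),
              sum(x$hpa != x$msp)))
  invisible(x)
}

MSAP_STATES <- c("UNMETHYLATED", "INTERNAL_METHYLATED",
                 "HEMI_METHYLATED", "UNINFORMATIVE")

#' Classify the methylation state of every CCGG site in a profile
#'
#' Applies the standard MSAP isoschizomer logic per site: a band in both
#' patterns means the site is unmethylated; a band only in the MspI pattern
#' means the internal cytosine is methylated; a band only in the HpaII
#' pattern means the external cytosine is hemi-methylated; no band in either
#' pattern is uninformative (full methylation blocks both digests).
#'
#' @param profile an [msap_profile()].
#' @return A factor of length `n_sites` with levels `UNMETHYLATED`,
#'   `INTERNAL_METHYLATED`, `HEMI_METHYLATED`, `UNINFORMATIVE`, named by
#'   site id.
#' @export
classify_site_states <- function(profile) {
  stopifnot(inherits(profile, "msap_profile"))
  state <- ifelse(profile$hpa == 1L & profile$msp == 1L, "UNMETHYLATED",
           ifelse(profile$hpa == 0L & profile$msp == 1L, "INTERNAL_METHYLATED",
           ifelse(profile$hpa == 1L & profile$msp == 0L, "HEMI_METHYLATED",
                  "UNINFORMATIVE")))
  out <- factor(state, levels = MSAP_STATES)
  names(out) <- profile$site_ids
  out
}

#' Per-individual cytosine methylation level
#'
#' The methylation level is the number of polymorphic bands between the
#' HpaII and MspI patterns of one individual divided by the number of loci
#' carrying a band in at least one pattern. Sites absent from both patterns
#' contribute no bands; with `denominator = "all"` they are counted anyway.
#'
#' @param profile an [msap_profile()].
#' @param denominator `"informative"` (default; sites with a band in either
#'   pattern) or `"all"` (every site).
#' @return Fraction in `[0, 1]`.
#' @export
methylation_level <- function(profile,
                              denominator = c("informative", "all")) {
  stopifnot(inherits(profile, "msap_profile"))
  denominator <- match.arg(denominator)
  poly <- sum(profile$hpa != profile$msp)
  denom <- if (denominator == "all") length(profile$hpa)
           else sum(profile$hpa == 1L | profile$msp == 1L)
  if (denom == 0L)
    stopf("methylation level undefined: no band in either pattern for '%s'",
          profile$individual_id)
  poly / denom
}

#' Group-wise methylation level summary
#'
#' @param profiles list of [msap_profile()] objects covering one or more
#'   groups.
#' @param denominator passed to [methylation_level()].
#' @return `data.frame` with one row per group: `group`, `n`, `mean`, `sd`
#'   (fractions) and `mean_pct`, `sd_pct`. A single-individual group reports
#'   `sd = 0` by convention.
#' @export
group_methylation_summary <- function(profiles,
                                      denominator = c("informative", "all")) {
  denominator <- match.arg(denominator)
  groups <- vapply(profiles, function(p) p$group, character(1))
  levels_ <- vapply(profiles, methylation_level, numeric(1),
                    denominator = denominator)
  present <- GROUPS[GROUPS %in% groups]
  if (length(present) == 0L) stopf("no profiles supplied")
  out <- do.call(rbind, lapply(present, function(g) {
    x <- levels_[groups == g]
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               stringsAsFactors = FALSE)
  }))
  out$mean_pct <- 100 * out$mean
  out$sd_pct <- 100 * out$sd
  rownames(out) <- NULL
  out
}

site_polymorphic <- function(profile) profile$hpa != profile$msp

#' Consensus methylation polymorphism of a replicate group
#'
#' A site is group-polymorphic when a strict majority of the group's
#' replicates show a HpaII/MspI band difference at that site; an exact tie
#' counts as not polymorphic.
#'
#' @param profiles list of [msap_profile()] objects from one group, sharing
#'   the same site index.
#' @return Named logical vector over sites.
#' @export
consensus_polymorphism <- function(profiles) {
  if (length(profiles) == 0L) stopf("need at least one replicate")
  ids <- profiles[[1L]]$site_ids
  for (p in profiles)
    if (!identical(p$site_ids, ids))
      stopf("site index mismatch between replicates")
  votes <- Reduce(`+`, lapply(profiles, site_polymorphic))
  out <- votes > length(profiles) / 2
  names(out) <- ids
  out
}

#' Call demethylation and hypermethylation events in the hybrid
#'
#' A site that is consensus-polymorphic in the parents but not in the
#' hybrid is a demethylation event in the hybrid; a site polymorphic only
#' in the hybrid is a hypermethylation event. Parent-side polymorphism
#' defaults to at least one parent group (`parent_rule = "any"`); `"both"`
#' requires both parents.
#'
#' @param parent_profiles list of [msap_profile()] objects for the two parent
#'   groups (`MH`, `MA`).
#' @param hybrid_profiles list of [msap_profile()] objects for the `F4`
#'   group.
#' @param parent_rule `"any"` (default) or `"both"`: how many parent groups
#'   must be polymorphic for a demethylation call.
#' @return `data.frame` with columns `site_id`, `event_type`
#'   (`DEMETHYLATION`/`HYPERMETHYLATION`), and the per-group consensus flags
#'   `poly_MH`, `poly_MA`, `poly_F4`. Zero rows when nothing is called.
#' @export
call_events <- function(parent_profiles, hybrid_profiles,
                        parent_rule = c("any", "both")) {
  parent_rule <- match.arg(parent_rule)
  groups <- vapply(parent_profiles, function(p) p$group, character(1))
  mh <- parent_profiles[groups == "MH"]
  ma <- parent_profiles[groups == "MA"]
  if (length(mh) == 0L || length(ma) == 0L)
    stopf("both parent groups (MH, MA) must be non-empty")
  if (length(hybrid_profiles) == 0L) stopf("F4 group must be non-empty")
  poly_mh <- consensus_polymorphism(mh)
  poly_ma <- consensus_polymorphism(ma)
  poly_f4 <- consensus_polymorphism(hybrid_profiles)
  if (!identical(names(poly_mh), names(poly_f4)) ||
      !identical(names(poly_ma), names(poly_f4)))
    stopf("site index mismatch between groups")
  parent_poly <- if (parent_rule == "any") poly_mh | poly_ma
                 else poly_mh & poly_ma
  demeth <- parent_poly & !poly_f4
  hyper <- poly_f4 & !poly_mh & !poly_ma
  idx <- which(demeth | hyper)
  data.frame(site_id = names(poly_f4)[idx],
             event_type = ifelse(demeth[idx], "DEMETHYLATION",
                                 "HYPERMETHYLATION"),
             poly_MH = unname(poly_mh[idx]),
             poly_MA = unname(poly_ma[idx]),
             poly_F4 = unname(poly_f4[idx]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read MSAP band CSV exports into paired profiles
#'
#' Expects one file per individual per enzyme named
#' `bands_<individual>_<enzyme>.csv` (`enzyme` is `HpaII` or `MspI`) with
#' header `site_id,present`. The two enzyme files of an individual are joined
#' on `site_id`; a site present in one file only is treated as absent (0) in
#' the other, with a warning.
#'
#' @param dir directory containing the band CSV files.
#' @param groups named character vector mapping individual id to group; when
#'   `NULL` the group is taken from the prefix of the individual id (text
#'   before the first underscore).
#' @return List of [msap_profile()] objects.
#' @export
read_msap_bands <- function(dir, groups = NULL) {
  files <- list.files(dir, pattern = "^bands_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0L) stopf("no bands_*.csv files in '%s'", dir)
  meta <- sub("^bands_(.*)_(HpaII|MspI)\\.csv$", "\\1|\\2", basename(files))
  bad <- !grepl("|", meta, fixed = TRUE)
  if (any(bad)) stopf("unrecognised band file name: %s", basename(files)[bad][1L])
  ind <- sub("\\|.*$", "", meta)
  enz <- sub("^.*\\|", "", meta)
  out <- list()
  for (id in unique(ind)) {
    fh <- files[ind == id & enz == "HpaII"]
    fm <- files[ind == id & enz == "MspI"]
    if (length(fh) != 1L || length(fm) != 1L)
      stopf("individual '%s' needs exactly one HpaII and one MspI file", id)
    h <- utils::read.csv(fh, stringsAsFactors = FALSE)
    m <- utils::read.csv(fm, stringsAsFactors = FALSE)
    sites <- union(h$site_id, m$site_id)
    if (!setequal(h$site_id, m$site_id))
      warning(sprintf("individual '%s': site sets differ between enzymes; %s",
                      id, "missing sites treated as absent (0)"))
    hv <- h$present[match(sites, h$site_id)]; hv[is.na(hv)] <- 0L
    mv <- m$present[match(sites, m$site_id)]; mv[is.na(mv)] <- 0L
    grp <- if (!is.null(groups)) unname(groups[[id]])
           else sub("_.*$", "", id)
    out[[id]] <- msap_profile(id, grp, sites, hv, mv)
  }
  out
}

#' Write MSAP stage outputs
#'
#' Writes `states.tsv` (site by individual state matrix), `levels.tsv`
#' (individual, group, methylation level) and `events.tsv` to `dir`.
#'
#' @param profiles list of [msap_profile()] objects (all groups).
#' @param dir output directory (created if missing).
#' @param denominator passed to [methylation_level()].
#' @param parent_rule passed to [call_events()].
#' @return Invisibly, a list with elements `states`, `levels`, `summary`,
#'   `events`.
#' @export
run_msap <- function(profiles, dir = NULL,
                     denominator = c("informative", "all"),
                     parent_rule = c("any", "both")) {
  denominator <- match.arg(denominator)
  parent_rule <- match.arg(parent_rule)
  groups <- vapply(profiles, function(p) p$group, character(1))
  states <- do.call(cbind, lapply(profiles, function(p)
    as.character(classify_site_states(p))))
  colnames(states) <- vapply(profiles, function(p) p$individual_id,
                             character(1))
  rownames(states) <- profiles[[1L]]$site_ids
  lv <- data.frame(
    individual = colnames(states), group = groups,
    level = vapply(profiles, methylation_level, numeric(1),
                   denominator = denominator),
    stringsAsFactors = FALSE)
  events <- call_events(profiles[groups %in% c("MH", "MA")],
                        profiles[groups == "F4"], parent_rule = parent_rule)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(site_id = rownames(states), states,
                                  check.names = FALSE),
                       file.path(dir, "states.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(lv, file.path(dir, "levels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(events, file.path(dir, "events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(states = states, levels = lv,
                 summary = group_methylation_summary(profiles,
                                                     denominator = denominator),
                 events = events))
}
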