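test_that("site states follow the isoschizomer logic", {
  p <- msap_profile("x", "MH", paste0("s", 1:4),
                    hpa = c(1, 0, 1, 0), msp = c(1, 1, 0, 0))
  st <- classify_site_states(p)
  expect_equal(unname(as.character(st)),
               c("UNMETHYLATED", "INTERNAL_METHYLATED", "HEMI_METHYLATED",
                 "UNINFORMATIVE"))
  expect_named(st, paste0("s", 1:4))
  # state partition: exactly one state per site
  expect_equal(sum(table(st)), 4L)
})

test_that("profile constructor validates inputs", {
  expect_error(msap_profile("x", "XX", "s1", 1, 1), "group")
  expect_error(msap_profile("x", "MH", c("s1", "s2"), 1, c(1, 0)),
               "equal length")
  expect_error(msap_profile("x", "MH", "s1", 2, 1), "binary")
  expect_error(msap_profile("x", "MH", c("s1", "s1"), c(1, 1), c(1, 1)),
               "duplicated")
})

test_that("methylation level is polymorphic over banded loci", {
  # 10 sites: 4 polymorphic, 6 present in both patterns, none absent
  p <- msap_profile("x", "MH", paste0("s", 1:10),
                    hpa = c(1, 1, 1, 1, 1, 1, 1, 0, 1, 0),
                    msp = c(1, 1, 1, 1, 1, 1, 0, 1, 0, 1))
  expect_equal(methylation_level(p), 0.4)

  all_poly <- msap_profile("y", "MH", paste0("s", 1:4),
                           hpa = c(1, 0, 1, 0), msp = c(0, 1, 0, 1))
  expect_equal(methylation_level(all_poly), 1)

  none <- msap_profile("z", "MH", paste0("s", 1:3), rep(1, 3), rep(1, 3))
  expect_equal(methylation_level(none), 0)

  blank <- msap_profile("w", "MH", paste0("s", 1:3), rep(0, 3), rep(0, 3))
  expect_error(methylation_level(blank), "undefined")
})

test_that("uninformative sites drop from the denominator unless asked", {
  p <- msap_profile("x", "F4", paste0("s", 1:5),
                    hpa = c(1, 0, 0, 0, 1), msp = c(0, 1, 0, 0, 1))
  expect_equal(methylation_level(p), 2 / 3)
  expect_equal(methylation_level(p, denominator = "all"), 2 / 5)
})

test_that("methylation level is invariant to site reordering", {
  set.seed(42)
  hpa <- rbinom(30, 1, 0.5); msp <- rbinom(30, 1, 0.5)
  hpa[1] <- 1  # guarantee a band
  p <- msap_profile("x", "MA", paste0("s", 1:30), hpa, msp)
  perm <- sample(30)
  p2 <- msap_profile("x", "MA", paste0("s", 1:30)[perm], hpa[perm],
                     msp[perm])
  expect_equal(methylation_level(p), methylation_level(p2))
})

test_that("group summary averages individuals and handles edge cases", {
  mk <- function(id, g, hpa) msap_profile(id, g, paste0("s", 1:4), hpa,
                                          rep(1, 4))
  profs <- list(mk("MH_1", "MH", c(0, 0, 1, 1)),   # level 0.5
                mk("MH_2", "MH", c(0, 1, 1, 1)),   # level 0.25
                mk("F4_1", "F4", c(0, 0, 0, 1)))   # level 0.75
  s <- group_methylation_summary(profs)
  expect_equal(s$mean[s$group == "MH"], 0.375)
  expect_equal(s$sd[s$group == "MH"], sd(c(0.5, 0.25)))
  # single individual: sd reported as 0 by convention
  expect_equal(s$sd[s$group == "F4"], 0)
  expect_equal(s$mean_pct[s$group == "F4"], 75)
  # two identical replicates
  s2 <- group_methylation_summary(list(mk("a", "MA", c(0, 1, 1, 1)),
                                       mk("b", "MA", c(0, 1, 1, 1))))
  expect_equal(s2$sd, 0)
})

test_that("consensus polymorphism uses strict majority with tie -> no", {
  mk <- function(id, hpa) msap_profile(id, "MH", "s1", hpa, 1)
  poly <- function(n_poly, n_total) {
    profs <- lapply(seq_len(n_total), function(i)
      mk(paste0("i", i), if (i <= n_poly) 0 else 1))
    unname(consensus_polymorphism(profs))
  }
  expect_true(poly(3, 4))
  expect_false(poly(2, 4))   # exact tie
  expect_true(poly(1, 1))
  expect_false(poly(0, 4))
})

test_that("event calling applies the parent/hybrid polymorphism rule", {
  # one site per scenario; single replicate per group
  mk <- function(g, hpa) msap_profile(paste0(g, "_1"), g,
                                      paste0("s", seq_along(hpa)), hpa,
                                      rep(1, length(hpa)))
  # sites: 1 polymorphic in MH only; 2 in F4 only; 3 in MH and F4;
  #        4 in all; 5 in none
  parents <- list(mk("MH", c(0, 1, 0, 0, 1)), mk("MA", c(1, 1, 1, 0, 1)))
  hybrid <- list(mk("F4", c(1, 0, 0, 0, 1)))
  ev <- call_events(parents, hybrid)
  expect_equal(ev$site_id, c("s1", "s2"))
  expect_equal(ev$event_type, c("DEMETHYLATION", "HYPERMETHYLATION"))
  # no site is both event types
  expect_false(any(duplicated(ev$site_id)))
  # "both parents" rule drops the MH-only demethylation call
  ev2 <- call_events(parents, hybrid, parent_rule = "both")
  expect_false("s1" %in% ev2$site_id[ev2$event_type == "DEMETHYLATION"])
})

test_that("event calling rejects mismatched site indices", {
  p1 <- msap_profile("MH_1", "MH", c("a", "b"), c(1, 0), c(0, 1))
  p2 <- msap_profile("MA_1", "MA", c("a", "c"), c(1, 0), c(0, 1))
  h <- list(msap_profile("F4_1", "F4", c("a", "b"), c(1, 1), c(1, 1)))
  expect_error(call_events(list(p1, p2), h), "mismatch")
  expect_error(call_events(list(p1), h), "non-empty")
})

test_that("band CSVs round-trip through write and read", {
  sim <- simulate_msap(msap_sim_spec(n_sites = 30, n_demeth_sites = 2,
                                     n_hyper_sites = 1,
                                     replicates_per_group = 2, seed = 7))
  d <- withr::local_tempdir()
  write_msap_bands(sim$profiles, d)
  back <- read_msap_bands(d)
  expect_setequal(names(back), names(sim$profiles))
  for (id in names(back)) {
    expect_equal(back[[id]]$hpa, sim$profiles[[id]]$hpa)
    expect_equal(back[[id]]$msp, sim$profiles[[id]]$msp)
    expect_equal(back[[id]]$group, sim$profiles[[id]]$group)
  }
})

test_that("a site missing from one enzyme file is read as absent", {
  d <- withr::local_tempdir()
  write.csv(data.frame(site_id = c("a", "b"), present = c(1, 1)),
            file.path(d, "bands_MH_1_HpaII.csv"), row.names = FALSE)
  write.csv(data.frame(site_id = "a", present = 1),
            file.path(d, "bands_MH_1_MspI.csv"), row.names = FALSE)
  expect_warning(profs <- read_msap_bands(d), "treated as absent")
  expect_equal(profs[["MH_1"]]$msp[profs[["MH_1"]]$site_ids == "b"], 0L)
})
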