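test_that("a single haplotype yields a core over the full window with no breakpoints", {
  pos <- seq(100, 700, by = 100)
  m <- matrix(rep(c(0L, 1L, 0L, 1L, 1L, 0L, 0L), 1), nrow = 1, byrow = TRUE)
  core <- shared_core(make_haps(m, pos), index_pos = 400)
  expect_equal(core$core$start, 100)
  expect_equal(core$core$end, 700)
  expect_true(all(core$per_family_breakpoints$side == "none"))
  expect_equal(core$n_haplotypes, 1L)
})

test_that("two identical haplotypes share the full window", {
  pos <- seq(100, 700, by = 100)
  h <- c(0L, 1L, 0L, 1L, 1L, 0L, 0L)
  core <- shared_core(make_haps(rbind(h, h), pos), index_pos = 400)
  expect_equal(c(core$core$start, core$core$end), c(100, 700))
  expect_length(core$discordant_sites, 0L)
})

test_that("planted discordances bound the core and attribute breakpoint sides", {
  # 7 sites, 5 haplotypes; family A deviates at site 2, family B at site 6
  pos <- seq(100, 700, by = 100)
  founder <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L)
  m <- rbind(founder, founder, founder, founder, founder)
  m[1, 2] <- 1L  # family A, centromeric side
  m[2, 6] <- 0L  # family B, telomeric side
  fams <- c("A", "B", "C", "D", "E")
  core <- shared_core(make_haps(m, pos, fams = fams), index_pos = 400)
  expect_equal(c(core$core$start, core$core$end), c(300, 500))
  bp <- core$per_family_breakpoints
  expect_equal(bp$side[bp$family == "A"], "centromeric")
  expect_equal(bp$centromeric_pos[bp$family == "A"], 200)
  expect_equal(bp$side[bp$family == "B"], "telomeric")
  expect_equal(bp$telomeric_pos[bp$family == "B"], 600)
  expect_true(all(bp$side[bp$family %in% c("C", "D", "E")] == "none"))
  # cross-check against the exhaustive oracle
  oc <- oracle_core(m, pos, index_idx = 4L)
  expect_equal(core$core$start, oc$start)
  expect_equal(core$core$end, oc$end)
})

test_that("wildcard-only columns never break the core but are listed as unresolved", {
  pos <- seq(100, 500, by = 100)
  m <- rbind(c(1L, NA, 0L, 1L, 0L),
             c(1L, NA, 0L, 1L, 0L))
  core <- shared_core(make_haps(m, pos), index_pos = 300)
  expect_equal(c(core$core$start, core$core$end), c(100, 500))
  expect_equal(core$unresolved_support, "chr17:200:A:G")
})

test_that("mismatched site lists and empty input are rejected", {
  pos <- seq(100, 300, by = 100)
  haps <- make_haps(rbind(c(1L, 0L, 1L)), pos)
  expect_error(shared_core(list(), 200), "at least one haplotype")
  other <- make_haps(rbind(c(1L, 0L, 1L)), pos + 5)
  expect_error(shared_core(c(haps, other), 200), "mismatched site lists")
  expect_error(shared_core(haps, 250), "not a haplotype site")
})

test_that("shared_core equals the exhaustive longest-run oracle on random sets", {
  set.seed(405)
  for (rep in 1:120) {
    n_sites <- sample(3:20, 1)
    n_hap <- sample(1:8, 1)
    pos <- sort(sample(1:10000, n_sites))
    idx <- sample(n_sites, 1)
    m <- matrix(sample(c(0L, 1L, NA), n_sites * n_hap, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2)), nrow = n_hap)
    m[, idx] <- 1L  # carriers all carry the index allele
    core <- shared_core(make_haps(m, pos), index_pos = pos[idx])
    oc <- oracle_core(m, pos, idx)
    expect_equal(core$core$start, oc$start)
    expect_equal(core$core$end, oc$end)
  }
})

test_that("breakpoint sides partition discordant families and match the oracle", {
  set.seed(406)
  for (rep in 1:60) {
    n_sites <- sample(5:20, 1)
    n_hap <- sample(2:8, 1)
    pos <- sort(sample(1:10000, n_sites))
    idx <- sample(n_sites, 1)
    m <- matrix(sample(c(0L, 1L, NA), n_sites * n_hap, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)), nrow = n_hap)
    m[, idx] <- 1L
    fams <- paste0("fam", seq_len(n_hap))
    core <- shared_core(make_haps(m, pos, fams = fams), index_pos = pos[idx])
    bp <- core$per_family_breakpoints
    # reported positions lie strictly outside the core on the stated side
    for (r in seq_len(nrow(bp))) {
      if (!is.na(bp$centromeric_pos[r]))
        expect_lt(bp$centromeric_pos[r], core$core$start)
      if (!is.na(bp$telomeric_pos[r]))
        expect_gt(bp$telomeric_pos[r], core$core$end)
      expect_true(bp$side[r] %in% c("none", "centromeric", "telomeric", "both"))
      if (bp$side[r] == "centromeric") expect_true(is.na(bp$telomeric_pos[r]))
      if (bp$side[r] == "telomeric") expect_true(is.na(bp$centromeric_pos[r]))
    }
    ob <- oracle_breakpoints(m, pos, fams,
                             b_lo = which(pos == core$core$start),
                             b_hi = which(pos == core$core$end))
    for (f in fams) {
      expect_equal(bp$side[bp$family == f], ob[[f]]$side, info = f)
      expect_equal(bp$centromeric_pos[bp$family == f], ob[[f]]$centromeric_pos)
      expect_equal(bp$telomeric_pos[bp$family == f], ob[[f]]$telomeric_pos)
    }
  }
})

test_that("adding a resolved haplotype never enlarges the core", {
  # monotonicity concerns resolved evidence: an extra haplotype can only
  # add discordance, shrinking the concordant run (an unresolved wildcard
  # column, by contrast, can later be resolved outward by a new haplotype,
  # which is support, not contradiction)
  set.seed(407)
  for (rep in 1:40) {
    n_sites <- sample(5:15, 1)
    pos <- sort(sample(1:5000, n_sites))
    idx <- sample(n_sites, 1)
    m <- matrix(sample(c(0L, 1L), n_sites * 5, replace = TRUE), nrow = 5)
    m[, idx] <- 1L
    haps <- make_haps(m, pos)
    for (k in 2:5) {
      small <- shared_core(haps[seq_len(k - 1L)], pos[idx])
      big <- shared_core(haps[seq_len(k)], pos[idx])
      expect_true(all(big$core_keys %in% small$core_keys))
    }
  }
})

test_that("span_kb floors the point-coordinate difference", {
  got <- span_kb(genomic_interval("chr17", 74819055, 74947323))
  expect_equal(as.integer(got), 128L)
  expect_equal(attr(got, "bp"), 128268)
  expect_equal(as.integer(span_kb(genomic_interval("chr1", 100, 100))), 0L)
  expect_equal(span_kb(genomic_interval("chr1", 1000, 2000)), 1L,
               ignore_attr = TRUE)
  expect_equal(attr(span_kb(genomic_interval("chr1", 1000, 2000)), "bp"), 1000)
})

singleton_case <- function(gts, pos = c(100, 200, 300)) {
  recs <- sprintf("chr17\t%d\t.\tA\tG\t.\tPASS\t.\tGT\t%s", pos, gts)
  read_vcf(write_test_vcf(recs, samples = "SG"))$calls
}

test_that("singleton interrogation checks consensus-allele presence per site", {
  cons <- c("chr17:100:A:G" = 1L, "chr17:200:A:G" = 0L, "chr17:300:A:G" = 1L)
  # carries every consensus allele het
  r1 <- interrogate_singleton(singleton_case(c("0/1", "0/1", "0/1")), "SG", cons)
  expect_equal(r1$verdict, "consistent")
  # ref/ref at a consensus-alt site
  r2 <- interrogate_singleton(singleton_case(c("0/0", "0/1", "0/1")), "SG", cons)
  expect_equal(r2$verdict, "inconsistent")
  expect_equal(r2$per_site$key[!r2$per_site$present], "chr17:100:A:G")
  # all genotypes missing
  r3 <- interrogate_singleton(singleton_case(c("./.", "./.", "./.")), "SG", cons)
  expect_equal(r3$verdict, "indeterminate")
  expect_equal(r3$n_untestable, 3L)
})

test_that("simulated founder carriers and non-carriers are separated by interrogation", {
  co <- simulate_cohort(sim_config(seed = 31))
  haps <- build_carrier_haplotypes(co$vcf, co$ped, co$freq, co$deletions,
                                   index_key = co$truth$index_key,
                                   gene = sim_config()$gene)
  core <- shared_core(haps, sim_config()$index_pos)
  # the simulated singleton carries the full founder segment
  expect_equal(interrogate_singleton(co$vcf$calls, "F5_CH", core)$verdict,
               "consistent")
  nc <- sim_noncarrier_calls(co, 25)
  verdicts <- vapply(unique(nc$sample), function(s)
    interrogate_singleton(nc, s, core)$verdict, "")
  expect_true(all(verdicts == "inconsistent"))
})
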