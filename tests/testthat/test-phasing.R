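test_that("informative-site selection respects window and frequency threshold", {
  gene <- genomic_interval("chr17", 74862454, 74873150)
  cfg <- phase_config(window_bp = 150000, maf_informative = 0.1)
  pos <- c(gene$start - 150001, gene$start - 150000, 74865000,
           gene$end + 150000, gene$end + 150001)
  af <- c(0.01, 0.01, 0.09, 0.11, 0.01)
  sites <- data.frame(chrom = "chr17", pos = pos, id = ".", ref = "A",
                      alt = "G", key = paste0("chr17:", pos, ":A:G"),
                      stringsAsFactors = FALSE)
  ft <- tempfile()
  writeLines(c("chrom\tpos\tref\talt\taf",
               sprintf("chr17\t%d\tA\tG\t%s", pos, af)), ft)
  freq <- read_frequency_table(ft)
  out <- select_informative(sites, freq, cfg, gene)
  # one site below either window edge and one above threshold are dropped
  expect_equal(out$pos, c(gene$start - 150000, 74865000))
})

test_that("the index variant is always selected regardless of frequency", {
  gene <- genomic_interval("chr17", 74862454, 74873150)
  sites <- data.frame(chrom = "chr17", pos = c(74864000, 74865062), id = ".",
                      ref = c("A", "C"), alt = c("G", "A"),
                      key = c("chr17:74864000:A:G", "chr17:74865062:C:A"),
                      stringsAsFactors = FALSE)
  ft <- tempfile()
  writeLines(c("chrom\tpos\tref\talt\taf",
               "chr17\t74864000\tA\tG\t0.4",
               "chr17\t74865062\tC\tA\t0.4"), ft)
  freq <- read_frequency_table(ft)
  expect_warning(
    out <- select_informative(sites, freq, phase_config(), gene,
                              index_key = "chr17:74865062:C:A"),
    "no informative SNVs besides the index")
  expect_equal(out$key, "chr17:74865062:C:A")
})

test_that("selection equals a brute-force re-filter on a 300 kb window", {
  set.seed(402)
  gene <- genomic_interval("chr17", 74862454, 74873150)
  cfg <- phase_config()
  pos <- sort(sample(seq(gene$start - 160000, gene$end + 160000), 40))
  af <- round(runif(40, 0, 0.5), 4)
  sites <- data.frame(chrom = "chr17", pos = pos, id = ".", ref = "A",
                      alt = "G", key = paste0("chr17:", pos, ":A:G"),
                      stringsAsFactors = FALSE)
  ft <- tempfile()
  writeLines(c("chrom\tpos\tref\talt\taf",
               sprintf("chr17\t%d\tA\tG\t%s", pos, af)), ft)
  out <- select_informative(sites, read_frequency_table(ft), cfg, gene)
  manual <- sites[af < 0.1 & pos >= gene$start - 150000 &
                    pos <= gene$end + 150000, ]
  expect_equal(out$key, manual$key[order(manual$pos)])
})

test_that("forced and uninformative trio configurations phase as expected", {
  child <- rbind(c(0L, 1L), c(0L, 1L), c(1L, 1L), c(NA, 1L))
  father <- rbind(c(0L, 0L), c(0L, 1L), c(0L, 1L), c(0L, 1L))
  mother <- rbind(c(0L, 1L), c(0L, 1L), c(0L, 1L), c(0L, 1L))
  ph <- phase_by_segregation(child, father, mother)
  # child het, father hom-ref: alt must be maternal
  expect_equal(ph$status[1], "resolved")
  expect_equal(ph$paternal[1], 0L)
  expect_equal(ph$maternal[1], 1L)
  # all het: uninformative
  expect_equal(ph$status[2], "unresolved")
  # hom child always resolved
  expect_equal(ph$status[3], "resolved")
  expect_equal(ph$paternal[3], 1L)
  # missing child allele
  expect_equal(ph$status[4], "missing")
})

test_that("Mendelian-impossible genotypes are flagged as conflicts", {
  ph <- phase_by_segregation(child = rbind(c(1L, 1L)),
                             father = rbind(c(0L, 0L)),
                             mother = rbind(c(0L, 1L)))
  expect_equal(ph$status, "mendel_conflict")
})

test_that("phase assignments match exhaustive enumeration on random error-free trios", {
  set.seed(403)
  for (rep in 1:100) {
    n <- sample(1:10, 1)
    tr <- random_trio(n)
    got <- phase_by_segregation(tr$child, tr$father, tr$mother)
    want <- oracle_phase_trio(tr$child, tr$father, tr$mother)
    expect_identical(got, want)
    # error-free transmission can never conflict
    expect_false(any(got$status == "mendel_conflict"))
    # resolved sites must recover the true transmitted alleles
    res <- got$status == "resolved"
    expect_equal(got$paternal[res], tr$truth_pat[res])
    expect_equal(got$maternal[res], tr$truth_mat[res])
  }
})

test_that("single-parent phasing matches enumeration with the other parent unknown", {
  set.seed(404)
  for (rep in 1:50) {
    tr <- random_trio(8)
    got <- phase_by_segregation(tr$child, father = tr$father)
    want <- oracle_phase_trio(tr$child, father = tr$father)
    expect_identical(got, want)
  }
})

hemizygous_setup <- function() {
  pos <- c(74818700, 74860000, 74888183, 74888184, 74950000)
  sites <- data.frame(chrom = "chr17", pos = pos, id = ".", ref = "C",
                      alt = "A", key = paste0("chr17:", pos, ":C:A"),
                      stringsAsFactors = FALSE)
  gts <- c("0/1", "0/1", "1/1", "0/1", "0/0")
  recs <- sprintf("chr17\t%d\t.\tC\tA\t.\tPASS\t.\tGT\t%s", pos, gts)
  v <- read_vcf(write_test_vcf(recs, samples = "HEMI"))
  list(sites = sites, calls = v$calls,
       del = genomic_interval("chr17", 74818633, 74888183))
}

test_that("hemizygous anchoring assigns in-deletion alleles to the index haplotype", {
  hs <- hemizygous_setup()
  hap <- anchor_hemizygous(hs$calls, "HEMI", "famH", hs$del, hs$sites,
                           index_key = "chr17:74860000:C:A")
  expect_true(hap$carries_index)
  # inside the deletion: any alt call -> alt on the retained haplotype
  expect_equal(hap$alleles[1:3], c(1L, 1L, 1L))
  expect_equal(hap$origin[1:3], rep("hemizygous_anchor", 3))
  # one bp beyond the deletion end: not anchored (het -> unresolved)
  expect_true(is.na(hap$alleles[4]))
  expect_equal(hap$origin[4], "unresolved")
  # outside, homozygous sites still resolve
  expect_equal(hap$alleles[5], 0L)
  expect_equal(hap$origin[5], "homozygous")
})

test_that("anchoring is refused when the index variant is outside the deletion", {
  hs <- hemizygous_setup()
  expect_error(
    anchor_hemizygous(hs$calls, "HEMI", "famH", hs$del, hs$sites,
                      index_key = "chr17:74950000:C:A"),
    "anchoring refused")
})

test_that("anchoring resolves a superset of what homozygosity alone resolves in the deletion", {
  co <- simulate_cohort(sim_config(seed = 19))
  del_sample <- co$deletions$sample[1]
  fam <- co$ped$family[co$ped$id == del_sample]
  sites <- select_informative(co$vcf$sites, co$freq, phase_config(),
                              sim_config()$gene, co$truth$index_key)
  del <- sample_deletions(co$deletions, del_sample)[[1]]
  anchored <- anchor_hemizygous(co$vcf$calls, del_sample, fam, del, sites,
                                co$truth$index_key)
  solo <- founderhap:::singleton_haplotype(co$vcf$calls, del_sample, fam,
                                           sites, co$truth$index_key)
  inside <- interval_contains(del, sites$chrom, sites$pos)
  solo_resolved <- which(inside & !is.na(solo$alleles))
  expect_true(all(!is.na(anchored$alleles[which(inside)])))
  expect_true(all(solo_resolved %in% which(!is.na(anchored$alleles))))
  # and where both resolve, they agree
  expect_equal(anchored$alleles[solo_resolved], solo$alleles[solo_resolved])
})

test_that("affected sibs sharing a transmitted chromosome yield one haplotype", {
  co <- simulate_cohort(sim_config(seed = 23))
  haps <- build_carrier_haplotypes(co$vcf, co$ped, co$freq, co$deletions,
                                   index_key = co$truth$index_key,
                                   gene = sim_config()$gene)
  fams <- vapply(haps, function(h) h$family, "")
  # the sib-pair family contributes one merged haplotype, not two
  expect_equal(sum(fams == "F2"), 1L)
  sib_hap <- haps[[which(fams == "F2")]]
  expect_match(sib_hap$individual, "\\+")
  expect_length(haps, 5L)
})

test_that("a parentless singleton resolves exactly its homozygous sites", {
  pos <- c(100, 200, 300)
  sites <- data.frame(chrom = "chr17", pos = pos, id = ".", ref = "A",
                      alt = "G", key = paste0("chr17:", pos, ":A:G"),
                      stringsAsFactors = FALSE)
  recs <- sprintf("chr17\t%d\t.\tA\tG\t.\tPASS\t.\tGT\t%s", pos,
                  c("0/0", "0/1", "1/1"))
  v <- read_vcf(write_test_vcf(recs, samples = "SOLO"))
  hap <- founderhap:::singleton_haplotype(v$calls, "SOLO", "famS", sites,
                                          "chr17:200:A:G")
  expect_equal(hap$alleles, c(0L, NA, 1L))
  expect_equal(hap$origin, c("homozygous", "unresolved", "homozygous"))
})

test_that("resolved haplotype positions match the generator's founder segment exactly", {
  co <- simulate_cohort(sim_config(seed = 29))
  haps <- build_carrier_haplotypes(co$vcf, co$ped, co$freq, co$deletions,
                                   index_key = co$truth$index_key,
                                   gene = sim_config()$gene)
  truth <- co$truth
  for (h in haps) {
    tf <- NULL
    for (f in truth$families) if (f$family == h$family) tf <- f
    expect_false(is.null(tf))
    in_segment <- h$sites$pos >= tf$segment_start & h$sites$pos <= tf$segment_end
    resolved <- !is.na(h$alleles)
    founder <- unname(truth$founder_alleles[h$sites$key])
    expect_equal(h$alleles[in_segment & resolved],
                 founder[in_segment & resolved],
                 info = paste("family", h$family))
    expect_true(h$carries_index)
  }
})
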