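test_that("5' start is strand-aware", {
  fr <- data.frame(start = c(1000L, 2000L, 500L, 500L),
                   end = c(1100L, 2100L, 501L, 501L),
                   strand = c("+", "-", "+", "-"))
  p5 <- fragment_5prime_start(fr)
  expect_equal(p5[1], 1000L)
  expect_equal(p5[2], 2099L)       # end - 1: length minus one adjustment
  expect_equal(p5[3], p5[4])       # length-1 fragment: same on both strands
})

test_that("nucleosome core windows are the central 61 bp, mirror-symmetric", {
  fwd <- nucleosome_core_window(1000L, "+")
  expect_equal(c(fwd$start, fwd$end), c(1052L, 1113L))
  rev <- nucleosome_core_window(2099L, "-")
  expect_equal(c(rev$start, rev$end), c(1987L, 2048L))
  expect_true(all(fwd$end - fwd$start == 61L))
  expect_true(all(rev$end - rev$start == 61L))

  # strand mirror symmetry: reflecting the genome maps + windows to -
  set.seed(13)
  L <- 100000L
  p5 <- sample(500:99000, 200)
  w_fwd <- nucleosome_core_window(p5, rep("+", 200))
  w_rev <- nucleosome_core_window((L - 1L) - p5, rep("-", 200))
  expect_identical(w_rev$start, (L - 1L) - (w_fwd$end - 1L))
  expect_identical(w_rev$end, (L - 1L) - w_fwd$start + 1L)
})

test_that("windows past the chromosome start are dropped and counted", {
  g <- tiny_genome()
  expect_message(
    w <- nucleosome_core_window(c(50L, 1000L), c("-", "+"),
                                chrom = "chr1", genome = g),
    "1 core window")
  expect_equal(nrow(w), 1L)
})

test_that("site depth matches the brute-force per-base oracle", {
  one <- data.table::data.table(chrom = "chr1", start = 100L, end = 161L)
  d <- site_depth(one, 0L, 300L)
  expect_equal(sum(d == 1L), 61L)
  expect_equal(sum(d), 61L)
  two <- rbind(one, one)
  expect_equal(sum(site_depth(two, 0L, 300L) == 2L), 61L)

  set.seed(5)
  starts <- sample(0:5000, 1000, replace = TRUE)
  w <- data.table::data.table(chrom = "chr1", start = starts,
                              end = starts + 61L)
  expect_identical(site_depth(w, 100L, 4000L), oracle_depth(w, 100L, 4000L))
})

test_that("bin copy ratios are counts over the median non-empty bin", {
  g <- declare_genome(c(chr1 = 1e6))
  # uniform: 100 5' ends per 100 kb bin -> ratio 1 everywhere
  starts <- as.integer(rep(seq(0, 1e6 - 1, by = 1e4), each = 1) +
                         rep(seq(0, 9999, length.out = 100), times = 100))
  starts <- sort(starts)[1:10000] %% as.integer(1e6 - 200)
  fr <- fragment_set("chr1", starts, starts + 167L, "+", g)
  b <- bin_copy_ratio(fr)
  expect_true(all(abs(b$ratio - 1) < 0.2))

  # one bin with 2x the median count -> ratio 2, log2 ratio 1
  per_bin <- rep(100L, 10)
  per_bin[4] <- 200L
  starts2 <- unlist(lapply(1:10, function(i)
    as.integer((i - 1) * 1e5 + seq(0, 99999, length.out = per_bin[i]))))
  fr2 <- fragment_set("chr1", starts2, starts2 + 100L, "+", g)
  b2 <- bin_copy_ratio(fr2)
  expect_equal(b2$ratio[4], 2)
  expect_equal(b2$log2_ratio[4], 1)
  expect_error(bin_copy_ratio(
    fragment_set(character(), integer(), integer(), character(), g)),
    "empty|zero fragments|no fragments")
})

test_that("CNV normalization divides by the linear bin ratio", {
  g <- declare_genome(c(chr1 = 3e5))
  bins <- data.table::data.table(
    chrom = "chr1", start = c(0L, 1e5, 2e5), end = c(1e5, 2e5, 3e5),
    bin = 1:3, count = c(100L, 200L, 100L), ratio = c(1, 2, 1),
    log2_ratio = c(0, 1, 0))
  depth <- rep(10, 300)
  norm <- cnv_normalize_depth(depth, bins, "chr1",
                              region_start = 100000L - 150L)
  expect_equal(norm[1:150], rep(10, 150))   # ratio-1 bin: identity
  expect_equal(norm[151:300], rep(5, 150))  # ratio-2 bin: halved
})

test_that("RDPKM follows its definition and averages transcripts", {
  # accumulated depth 500 over 2 kb with 1e6 mapped reads -> 250
  g_len <- 10000L
  depth <- rep(0, g_len)
  depth[2001:4000] <- 0.25   # sums to 500 over the [2000, 4000) window
  tss <- data.table::data.table(
    gene_id = "G1", transcript_id = "G1.1", chrom = "chr1",
    tss = 3000L, strand = "+")
  prof <- gene_rdpkm(list(chr1 = depth), tss, total_mapped = 1e6)
  expect_equal(unname(prof$rdpkm["G1"]), 500 / (2 * 1))
  # zero depth -> 0
  prof0 <- gene_rdpkm(list(chr1 = rep(0, g_len)), tss, total_mapped = 1e6)
  expect_equal(unname(prof0$rdpkm["G1"]), 0)
  # transcripts at RDPKM 100 and 300 -> gene mean 200
  depth2 <- rep(0, g_len)
  depth2[1001:3000] <- 0.1   # sum 200 -> RDPKM 100
  depth2[6001:8000] <- 0.3   # sum 600 -> RDPKM 300
  tss2 <- data.table::data.table(
    gene_id = "G2", transcript_id = c("G2.1", "G2.2"), chrom = "chr1",
    tss = c(2000L, 7000L), strand = "+")
  prof2 <- gene_rdpkm(list(chr1 = depth2), tss2, total_mapped = 1e6)
  expect_equal(unname(prof2$rdpkm["G2"]), 200)
  # invariant to jointly doubling depth and total_mapped
  prof3 <- gene_rdpkm(list(chr1 = 2 * depth2), tss2, total_mapped = 2e6)
  expect_equal(prof3$rdpkm, prof2$rdpkm)
  # off-chromosome transcript windows are skipped with a message
  tss3 <- rbind(tss2, data.table::data.table(
    gene_id = "G3", transcript_id = "G3.1", chrom = "chr1",
    tss = 500L, strand = "+"))
  expect_message(prof4 <- gene_rdpkm(list(chr1 = depth2), tss3, 1e6),
                 "skipped")
  expect_false("G3" %in% names(prof4$rdpkm))
})

test_that("gene filters use the published strict-< elimination rules", {
  profile <- structure(list(rdpkm = c(A = 99.9, B = 100, C = 5000,
                                      D = 150, E = 200)),
                       class = "rdpkm_profile")
  refs <- list(
    X = expression_reference(c(A = 8, B = 2, C = 1.0, D = 8, E = 4), "X"),
    Y = expression_reference(c(A = 8, B = 2, C = 9.0, D = 8, E = 4), "Y"))
  kept <- filter_genes(profile, refs)
  expect_false("A" %in% kept)  # RDPKM 99.9 < 100 removed
  expect_false("C" %in% kept)  # FPKM 1.0: log2 = 0 < 0.1 removed
  expect_true("B" %in% kept)   # RDPKM exactly 100 retained (strict <)
  expect_setequal(kept, c("B", "D", "E"))
  strict <- list(X = expression_reference(c(A = 0.5, B = 0.5, C = 0.5,
                                            D = 0.5, E = 0.5), "X"))
  expect_error(filter_genes(profile, strict), "no genes pass")
})

test_that("NPCC normalizes Pearson correlations to sum 1", {
  # formula oracle on constructed correlations
  r <- c(BRCA = 0.1, DLBC = 0.2, LIHC = 0.3)
  expect_equal(unname(r / sum(r)), c(1 / 6, 1 / 3, 1 / 2))

  set.seed(19)
  n <- 60
  x <- rlnorm(n, log(500), 0.3)
  refs <- lapply(c("BRCA", "DLBC", "LIHC"), function(tp)
    expression_reference(setNames(rlnorm(n, 1, 1), paste0("G", 1:n)), tp))
  names(refs) <- c("BRCA", "DLBC", "LIHC")
  profile <- structure(list(rdpkm = setNames(x, paste0("G", 1:n))),
                       class = "rdpkm_profile")
  npcc <- compute_npcc(profile, refs, retained = paste0("G", 1:n))
  expect_equal(sum(npcc$npcc), 1, tolerance = 1e-9)
  # r_raw equals the textbook two-pass Pearson oracle
  for (tp in names(refs))
    expect_equal(npcc$r_raw[[tp]],
                 oracle_pearson(x, as.numeric(refs[[tp]][paste0("G", 1:n)])),
                 tolerance = 1e-12)
  # equal correlations -> equal thirds
  y <- setNames(as.numeric(refs$BRCA[paste0("G", 1:n)]), paste0("G", 1:n))
  same <- list(A = expression_reference(y, "A"),
               B = expression_reference(y, "B"),
               C = expression_reference(y, "C"))
  npcc_eq <- compute_npcc(profile, same, retained = paste0("G", 1:n))
  expect_equal(unname(npcc_eq$npcc), rep(1 / 3, 3))
  # exactly cancelling correlations (r and -r) are rejected, not divided
  opp <- list(A = expression_reference(y, "A"),
              B = expression_reference(setNames(max(y) - y + min(y),
                                                names(y)), "B"))
  expect_error(compute_npcc(profile, opp, retained = paste0("G", 1:n)),
               "NPCC undefined")
})

test_that("whole pipeline removes a simulated CNV's coverage bias", {
  set.seed(9)
  refs <- simulate_expression_reference(60, seed = 9)
  tss <- simulate_tss(toy_genome(), 60, seed = 9)
  seg <- data.table::data.table(chrom = "chr1", start = 4e5, end = 14e5,
                                ratio = 2)
  fr <- simulate_fragments(fragment_sim_spec(
    "none", tss, refs, n_fragments = 60000L, cnv_segments = seg,
    seed = 9))
  b <- bin_copy_ratio(fr)
  inseg <- b$chrom == "chr1" & b$start >= 4e5 & b$end <= 14e5
  expect_equal(mean(b$ratio[inseg]), 2, tolerance = 0.1)
  # normalized mean depth inside vs outside the segment within 5%
  p5 <- fragment_5prime_start(fr)
  w <- nucleosome_core_window(p5, fr$strand, fr$chrom, toy_genome())
  cov <- mcanary:::windows_coverage(w, toy_genome())
  norm <- mcanary:::normalize_coverage(cov, b)
  m_in <- mean(as.numeric(S4Vectors::window(norm$chr1, 4e5 + 1, 14e5)))
  m_out <- mean(as.numeric(S4Vectors::window(norm$chr1, 1, 4e5)))
  expect_lt(abs(m_in / m_out - 1), 0.05)
})
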