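# Catalogs, NMF, refitting, indels, strand asymmetry, clustering.

toy_genome <- function(seq) list(contig = "chr1", length = nchar(seq),
                                 seq = seq)

test_that("catalog collapses purine substitutions into pyrimidine space", {
  g <- toy_genome("AAAAA")
  v <- data.frame(pos = 3, ref = "A", alt = "G")
  cat96 <- build_catalog(v, g)
  expect_equal(sum(cat96), 1)
  expect_equal(unname(cat96["T[T>C]T"]), 1)
  expect_true(all(build_catalog(v[0, ], g) == 0))
  expect_error(build_catalog(data.frame(pos = 3, ref = "C", alt = "G"), g),
               "mismatch")
})

test_that("catalog equals a per-variant naive recount on random input", {
  co <- shared_cohort()
  set.seed(8)
  pos <- sample(2:(co$genome$length - 1), 500)
  ref <- substring(co$genome$seq, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                        1), character(1), USE.NAMES = FALSE)
  v <- data.frame(pos = pos, ref = ref, alt = alt)
  cat96 <- build_catalog(v, co$genome)
  expect_equal(sum(cat96), 500)  # conservation
  # naive oracle: loop, reverse-complement by hand
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  naive <- setNames(integer(96), sbs_channels())
  for (i in seq_len(500)) {
    u <- substring(co$genome$seq, pos[i] - 1, pos[i] - 1)
    d <- substring(co$genome$seq, pos[i] + 1, pos[i] + 1)
    r <- ref[i]; a <- alt[i]
    if (r %in% c("A", "G")) {
      tmp <- comp[[u]]; u <- comp[[d]]; d <- tmp
      r <- comp[[r]]; a <- comp[[a]]
    }
    chan <- paste0(u, "[", r, ">", a, "]", d)
    naive[chan] <- naive[chan] + 1L
  }
  expect_equal(cat96, naive)
})

test_that("cosine similarity matches hand computations", {
  expect_equal(cosine_similarity(c(2, 3, 1), c(2, 3, 1)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero")
})

test_that("NMF recovers a planted rank-1 factorization", {
  sp <- generator_spectra()
  s <- sp[, "cpg_clock"]
  X <- outer(s, c(120, 80, 300))
  fit <- extract_signatures_nmf(X, rank = 1, n_restarts = 5, seed = 3)
  expect_gte(cosine_similarity(fit$W[, 1], s), 0.999)
  expect_true(all(abs(colSums(fit$W) - 1) < 1e-9))
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  # reconstruction: exposures recover the planted scales
  expect_equal(unname(fit$H[1, ]), c(120, 80, 300), tolerance = 0.01)
})

test_that("NMF objective is non-increasing and errors on bad rank", {
  sp <- generator_spectra()
  set.seed(5)
  X <- sp %*% matrix(runif(12, 10, 100), 4, 3)
  fit <- extract_signatures_nmf(X, rank = 2, n_iter = 100, n_restarts = 2,
                                seed = 1)
  expect_true(all(diff(fit$objective) <= 1e-8))
  expect_error(extract_signatures_nmf(X, rank = 10), "rank")
})

test_that("NMF is equivariant under column permutation", {
  sp <- generator_spectra()
  planted <- sp[, c("cpg_clock", "tcn", "oxid")]
  H0 <- cbind(diag(c(300, 280, 320)) + 15, diag(c(250, 260, 240)) + 10)
  X <- planted %*% H0
  perm <- c(3, 1, 2, 6, 4, 5)
  # exact symmetry: permuting the input columns together with the
  # initialization permutes the exposures and leaves signatures unchanged
  set.seed(9)
  init <- list(W = matrix(runif(96 * 3, 0.1, 1), 96, 3),
               H = matrix(runif(3 * 6, 0.1, 1), 3, 6))
  f1 <- extract_signatures_nmf(X, rank = 3, init = init)
  f2 <- extract_signatures_nmf(X[, perm], rank = 3,
                               init = list(W = init$W,
                                           H = init$H[, perm]))
  expect_equal(unname(f1$W), unname(f2$W), tolerance = 1e-8)
  expect_equal(unname(f1$H[, perm]), unname(f2$H), tolerance = 1e-8)
})

test_that("NNLS refit recovers exact mixtures and prunes weak signatures", {
  sp <- generator_spectra()
  # pure signature
  r <- refit_exposures(100 * sp[, "tcn"], sp)
  expect_equal(unname(r$contributions["tcn"]), 1.0, tolerance = 1e-9)
  expect_equal(unname(r$exposures["tcn"]), 100, tolerance = 1e-6)
  # noiseless 60/40 mixture
  cat60 <- 0.6 * 500 * sp[, "cpg_clock"] + 0.4 * 500 * sp[, "flat_clock"]
  r2 <- refit_exposures(cat60, sp)
  expect_equal(unname(r2$contributions[c("cpg_clock", "flat_clock")]),
               c(0.6, 0.4), tolerance = 1e-6)
  expect_setequal(r2$dropped, c("tcn", "oxid"))
  # degenerate input flagged
  r0 <- refit_exposures(numeric(96), sp)
  expect_true(r0$flagged)
  expect_true(all(is.na(r0$contributions)))
  # interior solution agrees with unconstrained least squares
  y <- as.numeric(sp %*% c(50, 80, 30, 60))
  x_lm <- unname(coef(lm(y ~ 0 + ., data = as.data.frame(sp))))
  x_nn <- unname(refit_exposures(y, sp, prune_threshold = 0)$exposures)
  expect_equal(x_nn, x_lm, tolerance = 1e-6)
})

test_that("indel catalog classifies by size and homopolymer run", {
  g <- toy_genome("ACGTTTTTTACGAAGCTA")
  # 1 bp T insertion inside the TTTTTT run (run length 6 -> long)
  ins_long <- data.frame(pos = 4, ref = "T", alt = "TT")
  # 1 bp G insertion after position 2 (run length 1 -> short)
  ins_short <- data.frame(pos = 2, ref = "C", alt = "CG")
  # 1 bp deletion of a T in the run -> long
  del_long <- data.frame(pos = 4, ref = "TT", alt = "T")
  # 3 bp deletion
  del3 <- data.frame(pos = 12, ref = "GAAG", alt = "G")
  cat6 <- build_indel_catalog(rbind(ins_long, ins_short, del_long, del3), g)
  expect_equal(unname(cat6["ins1_homlong"]), 1)
  expect_equal(unname(cat6["ins1_homshort"]), 1)
  expect_equal(unname(cat6["del1_homlong"]), 1)
  expect_equal(unname(cat6["del_2plus"]), 1)
  expect_equal(sum(cat6), 4)  # conservation
})

test_that("strand asymmetry counts pyrimidine strand vs transcript strand", {
  # 16 T>C with pyrimidine on the transcribed strand, 4 untranscribed:
  # gene on "+", pyrimidine on "-" (ref A) -> transcribed
  v <- data.frame(
    ref = c(rep("A", 16), rep("T", 4)),
    alt = c(rep("G", 16), rep("C", 4)),
    tx_strand = "+")
  sa <- strand_asymmetry(v)
  row <- sa[sa$type == "T>C", ]
  expect_equal(row$transcribed, 16)
  expect_equal(row$untranscribed, 4)
  expect_equal(row$p_value, binom.test(16, 20, 0.5)$p.value,
               tolerance = 1e-9)
  expect_equal(row$p_value, 0.0118, tolerance = 1e-2)
  # symmetric counts -> ratio 1, p = 1; swap invariance
  v2 <- data.frame(ref = c(rep("A", 10), rep("T", 10)),
                   alt = c(rep("G", 10), rep("C", 10)), tx_strand = "+")
  row2 <- strand_asymmetry(v2)[5, ]
  expect_equal(row2$ratio, 1.0)
  expect_equal(row2$p_value, 1.0)
  v2$tx_strand <- "-"
  row3 <- strand_asymmetry(v2)[5, ]
  expect_equal(row3$p_value, row2$p_value)
  # intergenic variants excluded
  v3 <- rbind(v, data.frame(ref = "T", alt = "C", tx_strand = NA))
  expect_equal(sum(strand_asymmetry(v3)[, c("transcribed",
                                            "untranscribed")]), 20)
})

test_that("exposure clustering orders by cosine distance deterministically", {
  E <- rbind(a = c(1, 0), b = c(0, 1), c = c(0.9, 0.1))
  hc <- cluster_exposures(E)
  # (1,0) merges with (0.9,0.1) before (0,1)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first, c("a", "c"))
  expect_equal(hc$height[1], 1 - cosine_similarity(c(1, 0), c(0.9, 0.1)),
               tolerance = 1e-12)
  # identical profiles merge at distance 0
  E2 <- rbind(x = c(2, 1), y = c(4, 2), z = c(0, 1))
  expect_equal(cluster_exposures(E2)$height[1], 0, tolerance = 1e-12)
  # singleton
  s <- cluster_exposures(E[1, , drop = FALSE])
  expect_s3_class(s, "singleton_dendrogram")
  # input order does not change the tree
  hc2 <- cluster_exposures(E[c(2, 3, 1), ])
  expect_identical(hc$labels, hc2$labels)
  expect_equal(hc$height, hc2$height)
})
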