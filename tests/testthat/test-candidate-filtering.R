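# Selection criteria and the seven-stage cascade.

test_that("isoelectric point reproduces the two-group closed form", {
  # blocked termini, one Asp (pKa 3.9) + one Lys (pKa 10.8): midpoint
  expect_equal(isoelectric_point("DK", termini = FALSE), (3.9 + 10.8) / 2,
               tolerance = 1e-3)
  # poly-Asp never positive without termini: boundary convention
  expect_warning(pid <- isoelectric_point("DDDD", termini = FALSE),
                 "never positive")
  expect_equal(pid, 0)
})

test_that("bisection agrees with a fine grid scan of the charge function", {
  full <- "ACDEFGHIKLMNPQRSTVWY"
  grid <- seq(0, 14, by = 1e-4)
  scan_pi <- function(s) grid[which.min(abs(net_charge(s, grid)))]
  expect_lt(abs(isoelectric_point(full) - scan_pi(full)), 1e-3)
  set.seed(14)
  for (k in 1:25) {
    s <- paste(sample(cpdesign:::AA1, 30, replace = TRUE), collapse = "")
    expect_lt(abs(suppressWarnings(isoelectric_point(s)) - scan_pi(s)),
              1e-3)
  }
})

test_that("formal charge counts composition with a strict boundary", {
  expect_equal(formal_charge("KKDE"), 0)
  expect_equal(formal_charge("KKKKKK"), 6)
  expect_false(abs(formal_charge("KKKKKK")) < 6)  # fails the strict rule
  set.seed(3)
  for (k in 1:20) {
    s <- sample(cpdesign:::AA1, 50, replace = TRUE)
    expect_equal(formal_charge(paste(s, collapse = "")),
                 sum(s %in% c("K", "R")) - sum(s %in% c("D", "E")))
  }
})

test_that("BLOSUM similarity is a best-hit lookup sum", {
  msa <- make_reference_msa(msa_config("ACDEFGHIKL", 5, 0.3, seed = 2))
  m62 <- blosum_matrix("BLOSUM62")
  # identity: best hit is the self-score when the query is a reference
  q <- msa$seq[3]
  bs <- blosum_similarity(q, msa, "BLOSUM62")
  qv <- strsplit(q, "")[[1]]
  expect_equal(bs$best, sum(m62[cbind(qv, qv)]))
  # per-cell lookup oracle against the canonical matrix
  q2 <- "ACDEFGHIKL"
  bs2 <- blosum_similarity(q2, msa, "BLOSUM62")
  oracle <- vapply(msa$seq, function(ref) {
    rv <- strsplit(ref, "")[[1]]
    sum(vapply(1:10, function(i) m62[strsplit(q2, "")[[1]][i], rv[i]],
               numeric(1)))
  }, numeric(1))
  expect_equal(unname(bs2$scores), unname(oracle))
  expect_equal(bs2$best, max(oracle))
  # empty position subset scores zero; length mismatch errors
  expect_equal(blosum_similarity(q2, msa, positions = integer())$best, 0)
  expect_error(blosum_similarity("ACD", msa), "width")
})

test_that("BLOSUM40 matrix is consistent with its defining symmetry", {
  m40 <- blosum_matrix("BLOSUM40")
  expect_true(isSymmetric(m40))
  expect_true(all(diag(m40) > 0))
  expect_equal(dim(m40), c(20, 20))
})

test_that("drastic mutation counting uses the inclusive threshold", {
  expect_equal(drastic_mutation_count("ACDEF", "ACDEF"), 0)
  # N -> G scores exactly 0 > -2; D -> G is -1; K -> D is -1; W -> G -2
  m62 <- blosum_matrix("BLOSUM62")
  expect_equal(m62["W", "G"], -2L)
  expect_equal(drastic_mutation_count("GCDEF", "WCDEF"), 1)  # exactly -2
  set.seed(6)
  for (k in 1:20) {
    wt <- sample(cpdesign:::AA1, 30, replace = TRUE)
    mu <- wt
    idx <- sample(30, 8)
    mu[idx] <- sample(cpdesign:::AA1, 8, replace = TRUE)
    oracle <- sum(mu != wt & m62[cbind(wt, mu)] <= -2)
    expect_equal(drastic_mutation_count(paste(mu, collapse = ""),
                                        paste(wt, collapse = "")), oracle)
  }
  expect_error(drastic_mutation_count("AC", "A"), "equal lengths")
})

test_that("cavity detection distinguishes closed shells from open ones", {
  expect_equal(length(detect_cavities(matrix(0, 1, 3), 1.9)), 0)
  shell <- cpdesign:::sphere_points(120) * 6
  v <- detect_cavities(shell, rep(1.5, 120), spacing = 1.0, probe = 1.4)
  expect_equal(length(v), 1)
  analytic <- 4 / 3 * pi * (6 - 1.5 - 1.4)^3
  expect_lt(abs(v - analytic) / analytic, 0.2)
  # 10 A aperture: flood fill escapes
  open <- shell[shell[, 3] < 6 * cos(asin(5 / 6)), ]
  expect_equal(length(detect_cavities(open, rep(1.5, nrow(open)))), 0)
  expect_error(detect_cavities(shell, rep(1.5, 120), spacing = -1),
               "spacing")
})

test_that("fold-recognition rule keeps strictly-above-mean long good hits", {
  same <- tibble::tibble(id = c("a", "b"), family = "PDZ",
                         log10_evalue = c(-40, -40),
                         match_length = c(10L, 10L))
  expect_equal(length(apply_fold_recognition_filter(same)), 0)
  two <- tibble::tibble(id = c("a", "b"), family = "PDZ",
                        log10_evalue = c(-40, -40),
                        match_length = c(10L, 20L))
  expect_equal(apply_fold_recognition_filter(two), "b")
  # brute-force scan on a synthetic table
  tab <- make_fold_recognition_table(500, 0.6, seed = 21)
  got <- apply_fold_recognition_filter(tab)
  want <- tab$id[tab$match_length > mean(tab$match_length) &
                   tab$log10_evalue < -31]
  expect_identical(got, want)
})

test_that("the cascade reproduces planted ground truth stage by stage", {
  bench <- make_cascade_benchmark(seed = 3)
  rep <- run_cascade(bench$archive, bench$structures, bench$references,
                     bench$records, bench$wildtype, bench$config)
  # expected per-stage survivor counts from the planted group sizes
  truth <- bench$truth
  order_of <- c(energy_top_n = 1, isoelectric_point = 2,
                fold_recognition = 3, similarity = 4, cavity = 5,
                charge = 6, drastic_mutations = 7)
  remaining <- nrow(truth)
  for (st in names(order_of)) {
    removed <- sum(truth$expected_stage == st, na.rm = TRUE)
    expect_equal(rep$stages$n_in[rep$stages$stage == st], remaining)
    expect_equal(rep$stages$n_out[rep$stages$stage == st],
                 remaining - removed)
    remaining <- remaining - removed
  }
  expect_equal(nrow(rep$survivors), sum(is.na(truth$expected_stage)))
  # counts monotone non-increasing; eliminations + survivors add up
  expect_true(all(diff(rep$stages$n_out) <= 0))
  expect_true(all(rep$stages$n_out <= rep$stages$n_in))
  expect_equal(rep$stages$n_out[7], nrow(rep$survivors))
  # per-sequence elimination stages match the plant exactly
  el <- elimination_stage(rep)
  j <- dplyr::left_join(truth, el, by = "id")
  expect_identical(j$eliminated_by, j$expected_stage)
})

test_that("stage order matters only where means are involved", {
  bench <- make_cascade_benchmark(seed = 8)
  base_rep <- run_cascade(bench$archive, bench$structures,
                          bench$references, bench$records, bench$wildtype,
                          bench$config)
  survivors <- sort(base_rep$survivors$id)
  # stages 5-7 are per-sequence predicates: applying them in any order to
  # the stage-4 survivor set gives the same final set
  s4 <- base_rep$decisions
  ids4 <- s4$id[s4$stage == "similarity" & s4$pass]
  pred_cavity <- s4$pass[match(paste(ids4, "cavity"),
                               paste(s4$id, s4$stage))]
  pred_charge <- s4$pass[match(paste(ids4, "charge"),
                               paste(s4$id, s4$stage))]
  # recompute charge/drastic predicates independently of stage order
  seqs <- bench$archive$sequence[match(ids4, bench$archive$id)]
  p_cav <- vapply(ids4, function(id) {
    st <- bench$structures[[id]]
    v <- detect_cavities(as.matrix(st[, c("x", "y", "z")]), st$radius)
    (if (length(v)) max(v) else 0) <= bench$config$cavity_max_volume
  }, logical(1))
  p_chg <- abs(vapply(seqs, formal_charge, integer(1))) <
    bench$config$charge_max
  p_dra <- vapply(seqs, function(s) {
    drastic_mutation_count(s, bench$wildtype)
  }, integer(1)) <= bench$config$drastic_max
  expect_identical(sort(ids4[p_cav & p_chg & p_dra]), survivors)
  # the similarity stage is order-sensitive: restricting its input set
  # changes the mean and can change who survives it
  sim_ids <- s4$id[s4$stage == "similarity"]
  sim_vals <- s4$value[s4$stage == "similarity"]
  low_half <- sim_ids[sim_vals <= stats::median(sim_vals)]
  m_all <- mean(sim_vals)
  m_low <- mean(sim_vals[sim_ids %in% low_half])
  expect_false(isTRUE(all.equal(m_all, m_low)))
})

test_that("cascade handles empty and missing inputs", {
  bench <- make_cascade_benchmark(seed = 3)
  empty <- bench$archive[0, ]
  rep0 <- run_cascade(empty, bench$structures, bench$references,
                      bench$records, bench$wildtype, bench$config)
  expect_true(all(rep0$stages$n_in == 0))
  expect_equal(nrow(rep0$survivors), 0)
  # a surviving sequence without a structure is reported by name
  no_struct <- bench$structures
  no_struct[["seq00200"]] <- NULL   # a clean passer
  expect_error(run_cascade(bench$archive, no_struct, bench$references,
                           bench$records, bench$wildtype, bench$config),
               "seq00200")
})
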