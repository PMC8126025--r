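toy_consensus <- function(profiles) {
  purrr::imap_dfr(profiles, function(x, comp) {
    tibble::tibble(compartment = comp, sample = seq_along(x),
                   consensus = x / sum(x), n_markers = 1L)
  })
}

test_that("scores are Pearson correlations with the textbook formula", {
  x <- c(0.05, 0.30, 0.40, 0.15, 0.10)
  y <- c(0.20, 0.25, 0.10, 0.25, 0.20)
  w <- profile_tbl(x)
  cons <- toy_consensus(list(A = x, B = y))
  s <- score_proteins(w, cons)
  expect_equal(s$score[s$compartment == "A"], 1.0, tolerance = 1e-12)
  expect_equal(s$score[s$compartment == "B"], pearson_oracle(x, y),
               tolerance = 1e-12)
})

test_that("scores are invariant to positive rescaling of the raw profile", {
  sim <- clean_sim()
  dw <- digital_westerns(sim$quant, sim$od280)
  cons <- build_consensus(dw, sim_marker_set(sim$truth))
  one <- dplyr::filter(dw, protein_id == dw$protein_id[1])
  scaled <- dplyr::mutate(one, rel_abundance = 7.3 * rel_abundance)
  expect_equal(score_proteins(scaled, cons)$score,
               score_proteins(one, cons)$score, tolerance = 1e-12)
})

test_that("all-zero profiles are unassigned and window mismatches error", {
  cons <- toy_consensus(list(A = c(1, 2, 3, 4)))
  w0 <- profile_tbl(c(0, 0, 0, 0))
  s <- score_proteins(w0, cons)
  expect_true(all(is.na(s$score)))
  expect_equal(assign_compartments(s)$assigned, "unassigned")
  w_short <- profile_tbl(c(1, 2, 3))
  expect_error(score_proteins(w_short, cons), class = "ffeprof_usage_error")
})

test_that("assignment applies the score and margin rules", {
  mk_scores <- function(...) {
    v <- c(...)
    tibble::tibble(protein_id = "p", compartment = names(v), score = v)
  }
  expect_equal(assign_compartments(mk_scores(PM = 0.95, ER = 0.40))$assigned,
               "PM")
  expect_equal(assign_compartments(mk_scores(PM = 0.85, TGN = 0.82))$assigned,
               "unassigned")
  expect_equal(assign_compartments(mk_scores(PM = 0.75, ER = 0.10))$assigned,
               "unassigned")
  tie <- assign_compartments(mk_scores(PM = 0.9, TP = 0.9))
  expect_equal(tie$assigned, "unassigned")
  expect_true(tie$tie)
})

test_that("assignment agrees with a brute-force rule evaluator on a grid", {
  # sweep all score triples on a 0.05 grid and compare with a direct
  # restatement of the rule
  grid <- seq(0, 1, by = 0.05)
  combos <- expand.grid(a = grid, b = grid, c = grid)
  combos <- combos[sample.int(nrow(combos), 400), ]  # subsample for speed
  scores <- tibble::tibble(
    protein_id = rep(sprintf("p%03d", seq_len(nrow(combos))), each = 3),
    compartment = rep(c("A", "B", "C"), nrow(combos)),
    score = as.vector(t(as.matrix(combos)))
  )
  got <- assign_compartments(scores, r_min = 0.8, margin_min = 0.1)
  got <- got[order(got$protein_id), ]
  want <- vapply(seq_len(nrow(combos)), function(i) {
    v <- sort(unlist(combos[i, ]), decreasing = TRUE)
    if (v[1] == v[2]) return("unassigned")
    if (v[1] < 0.8 || (v[1] - v[2]) < 0.1) return("unassigned")
    c("A", "B", "C")[which.max(unlist(combos[i, ]))]
  }, character(1))
  expect_equal(got$assigned, want)
})

test_that("population detection matches template structure", {
  tpl <- compartment_templates()
  prof <- template_profile(tpl) |>
    dplyr::filter(sample %in% 8:35) |>
    dplyr::group_by(compartment) |>
    dplyr::mutate(rel_abundance = density / sum(density)) |>
    dplyr::ungroup()
  # unimodal PM template: one population at sample 25
  pm <- dplyr::filter(prof, compartment == "PM") |>
    dplyr::rename(protein_id = compartment)
  pops_pm <- detect_populations(pm)
  expect_equal(nrow(pops_pm), 1)
  expect_equal(pops_pm$peak_sample, 25)
  # tonoplast-style template: anodic major in 13-19 plus minor at 24
  tp <- dplyr::filter(prof, compartment == "TP") |>
    dplyr::rename(protein_id = compartment)
  pops_tp <- detect_populations(tp)
  expect_equal(nrow(pops_tp), 2)
  expect_true(pops_tp$peak_sample[1] %in% 13:19)
  expect_equal(pops_tp$peak_sample[2], 24)
  expect_gt(pops_tp$mass[1], pops_tp$mass[2])
})

test_that("planted two-peak mixtures recover their mass split", {
  # 0.6 / 0.4 at samples 16 and 24; oracle: brute-force maxima scan and
  # basin summation on the noise-free discrete profile
  x <- 0.6 * discrete_gauss(16, 1.2, 1, 28) + 0.4 * discrete_gauss(24, 1.2, 1, 28)
  pops <- detect_populations(profile_tbl(x))
  expect_equal(nrow(pops), 2)
  expect_equal(pops$peak_sample, c(16, 24))
  expect_equal(pops$mass, c(0.6, 0.4), tolerance = 0.05)
  oracle <- populations_oracle(x, seq_along(x))
  expect_equal(pops$peak_sample, oracle$peak_sample)
  expect_equal(pops$mass, oracle$mass, tolerance = 1e-12)
})

test_that("population detection equals the brute-force oracle on random profiles", {
  set.seed(404)
  for (i in 1:200) {
    x <- stats::runif(28)^3
    x <- x / sum(x)
    got <- detect_populations(profile_tbl(x))
    want <- populations_oracle(x, 1:28)
    expect_equal(got$peak_sample, want$peak_sample)
    expect_equal(got$mass, want$mass, tolerance = 1e-12)
  }
})

test_that("population detection is symmetric under profile reversal", {
  set.seed(505)
  for (i in 1:50) {
    x <- stats::runif(28)^2
    x <- x / sum(x)
    fwd <- detect_populations(profile_tbl(x))
    rev_ <- detect_populations(profile_tbl(rev(x)))
    expect_equal(sort(29 - rev_$peak_sample), sort(fwd$peak_sample))
    expect_equal(rev_$mass[order(29 - rev_$peak_sample)],
                 fwd$mass[order(fwd$peak_sample)], tolerance = 1e-12)
  }
})

test_that("dual flags follow the window and native-mass logic", {
  sim <- clean_sim()
  dw <- digital_westerns(sim$quant, sim$od280)
  cons <- build_consensus(dw, sim_marker_set(sim$truth))
  windows <- compartment_windows(cons)
  native <- cons |>
    dplyr::rename(protein_id = compartment, rel_abundance = consensus) |>
    detect_populations() |>
    dplyr::rename(compartment = protein_id)

  # two populations inside the PM window: not dual
  pm_win <- dplyr::filter(windows, compartment == "PM")
  pops_pm <- tibble::tibble(protein_id = "x",
                            peak_sample = c(pm_win$start_sample[1],
                                            pm_win$end_sample[1]),
                            mass = c(0.6, 0.4))
  ref <- tibble::tibble(protein_id = "x", compartment = "PM")
  expect_false(flag_dual(pops_pm, windows, native, ref)$dual_flag[1])

  # populations in the tonoplast window (13-19) and the Golgi window
  # (23-24), far beyond the tonoplast's native cathodic share: dual
  pops_dual <- tibble::tibble(protein_id = "x", peak_sample = c(16, 24),
                              mass = c(0.55, 0.45))
  ref_tp <- tibble::tibble(protein_id = "x", compartment = "TP")
  expect_true(flag_dual(pops_dual, windows, native, ref_tp)$dual_flag[1])

  # a single population is never dual
  pops_one <- tibble::tibble(protein_id = "x", peak_sample = 24, mass = 1)
  expect_false(flag_dual(pops_one, windows, native, ref_tp)$dual_flag[1])

  # a tonoplast-like pattern with the native 80/20 split is explained
  pops_tp <- tibble::tibble(protein_id = "x", peak_sample = c(16, 24),
                            mass = c(0.8, 0.2))
  expect_false(flag_dual(pops_tp, windows, native, ref_tp)$dual_flag[1])

  # populations outside every window map to "none" and carry no evidence
  pops_none <- tibble::tibble(protein_id = "x", peak_sample = c(9, 11),
                              mass = c(0.5, 0.5))
  res_none <- flag_dual(pops_none, windows, native, ref_tp)
  expect_false(res_none$dual_flag[1])
  expect_true(all(res_none$mapped == "none"))
})

test_that("discordance compares assignment with annotation, HCM first", {
  assignments <- tibble::tibble(
    protein_id = c("p1", "p2", "p3", "p4", "p5"),
    assigned = c("TP", "PM", "unassigned", "TP", "GA")
  )
  ann <- tibble::tibble(
    protein_id = c("p1", "p2", "p3", "p4", "p5"),
    agi = NA_character_,
    hcm_compartment = c("PM", "PM", "PM", NA, NA),
    consensus_compartment = c("TP", NA, NA, NA, "GA,TP")
  )
  out <- flag_discordant(assignments, ann)
  expect_equal(out$discordant,
               c(TRUE,   # HCM says PM, profile says TP (HCM wins over cons.)
                 FALSE,  # agree
                 FALSE,  # unassigned never flagged
                 FALSE,  # unannotated never flagged
                 FALSE)) # consensus list contains the assignment
  expect_equal(out$annotated, c(TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("localize_proteins returns a coherent object with tidiers", {
  sim <- clean_sim()
  dw <- digital_westerns(sim$quant, sim$od280)
  loc <- localize_proteins(dw, sim_marker_set(sim$truth))
  expect_s3_class(loc, "ffe_localization")
  td <- tidy(loc)
  expect_equal(nrow(td), dplyr::n_distinct(dw$protein_id))
  gl <- glance(loc)
  expect_equal(gl$n_proteins, nrow(td))
  expect_equal(gl$n_assigned + gl$n_unassigned, gl$n_proteins)
  expect_output(print(loc), "ffe_localization")
})
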