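# one full-scale pair shared across this file's expectations
sca2_ens <- run_ensemble("sca2", default_schedule(), n = 1000, master_seed = 101)
sca3_ens <- run_ensemble("sca3", default_schedule(), n = 1000, master_seed = 101)

test_that("fate counts partition every ensemble", {
  for (ens in list(sca2_ens, sca3_ens)) {
    expect_equal(sum(ens$summary$counts), ens$n)
    expect_setequal(unique(ens$outcomes$status),
                    intersect(c("eliminated", "fixed_then_extinct",
                                "fixed_held", "persisting"),
                              unique(ens$outcomes$status)))
  }
  one <- run_ensemble("sca2", default_schedule(), n = 1, master_seed = 5)
  expect_equal(sum(one$summary$counts), 1L)
})

test_that("ensembles are bitwise reproducible under the master seed", {
  again <- run_ensemble("sca3", default_schedule(), n = 1000,
                        master_seed = 101)
  expect_identical(glance(again), glance(sca3_ens))
  expect_identical(again$outcomes, sca3_ens$outcomes)
  other <- run_ensemble("sca3", default_schedule(), n = 50, master_seed = 102)
  expect_false(identical(other$outcomes$terminal_generation[1:50],
                         sca3_ens$outcomes$terminal_generation[1:50]))
})

test_that("the two loci diverge in the expected directions", {
  g2 <- glance(sca2_ens)
  g3 <- glance(sca3_ens)
  expect_gt(g2$eliminated / g2$n_lineages, g3$eliminated / g3$n_lineages)
  expect_gt(g3$persisting / g3$n_lineages, 0.25)
  expect_lt(g2$persisting / g2$n_lineages, 0.05)
})

test_that("summaries compute order statistics per stratum and drop empty ones", {
  outcomes <- tibble::tibble(
    lineage_id = 1:3,
    status = "eliminated",
    terminal_generation = c(3L, 10L, 12L),
    fixation_generation = NA_integer_,
    repeat_at_event = c(60, 70, 80),
    ao_at_event = c(10, 11, 12),
    expanded_at_horizon = NA,
    frequency_at_horizon = NA_real_,
    repeat_at_horizon = NA_real_,
    seed = 1:3
  )
  s <- summarize_outcomes(outcomes)
  expect_equal(s$elimination_generation$median, 10)
  expect_equal(s$elimination_generation$min, 3)
  expect_equal(s$elimination_generation$max, 12)
  expect_null(s$fixation_generation) # no fixed stratum -> absent, not zero
  expect_null(s$frequency_at_horizon)
  expect_equal(s$counts[["eliminated"]], 3L)
  expect_error(summarize_outcomes(outcomes[0, ]), "non-empty")
})

test_that("summary medians bracket inside their ranges on real runs", {
  for (ens in list(sca2_ens, sca3_ens)) {
    s <- ens$summary
    for (f in c("elimination_generation", "fixation_generation",
                "repeat_at_elimination", "repeat_at_fixation")) {
      mr <- s[[f]]
      if (is.null(mr)) next
      expect_lte(mr$min, mr$median)
      expect_lte(mr$median, mr$max)
    }
  }
})

test_that("fractions converge between ensemble sizes", {
  small <- glance(run_ensemble("sca2", default_schedule(), n = 1000,
                               master_seed = 7))
  big <- glance(run_ensemble("sca2", default_schedule(), n = 4000,
                             master_seed = 8))
  for (f in c("eliminated", "fixed_then_extinct", "fixed_held",
              "persisting")) {
    p_small <- small[[f]] / 1000
    p_big <- big[[f]] / 4000
    se <- sqrt(max(p_small * (1 - p_small), 1e-6) / 1000)
    expect_lt(abs(p_big - p_small), 2 * se + 1e-12)
  }
})

test_that("the sensitivity sweep reproduces the main run at the preset SD", {
  sweep <- sensitivity_sweep("sca2", default_schedule(),
                             fitness_sd_values = 0.25, n = 1000,
                             master_seed = 101)
  expect_equal(nrow(sweep), 1)
  expect_equal(dplyr::select(sweep, -"fitness_sd", -"summary"),
               glance(sca2_ens))
  empty <- sensitivity_sweep("sca2", default_schedule(),
                             fitness_sd_values = numeric(0), n = 10,
                             master_seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("alternative fitness SDs leave the SCA2 fate profile intact", {
  sweep <- sensitivity_sweep("sca2", default_schedule(),
                             fitness_sd_values = c(0.1, 0.25, 0.5),
                             n = 400, master_seed = 11)
  expect_equal(nrow(sweep), 3)
  expect_true(all(sweep$eliminated / sweep$n_lineages > 0.85))
  expect_error(sensitivity_sweep("sca2", default_schedule(),
                                 fitness_sd_values = c(0.1, -1),
                                 n = 10, master_seed = 1),
               ">= 0")
})

test_that("disease comparisons test each fate class", {
  cmp <- compare_diseases(sca2_ens, sca3_ens)
  expect_equal(nrow(cmp), 4)
  expect_equal(cmp$count_a, as.integer(sca2_ens$summary$counts))
  expect_equal(cmp$count_b, as.integer(sca3_ens$summary$counts))
  elim_p <- cmp$p_value[cmp$fate == "eliminated"]
  pers_p <- cmp$p_value[cmp$fate == "persisting"]
  expect_lt(elim_p, 0.001)
  expect_lt(pers_p, 0.001)

  self <- compare_diseases(sca3_ens, sca3_ens)
  expect_true(all(self$count_a == self$count_b))
  expect_true(all(self$p_value == 1))

  small <- run_ensemble("sca2", default_schedule(), n = 10, master_seed = 1)
  expect_error(compare_diseases(sca2_ens, small), "unequal n")
})

test_that("tidy and glance expose the tabular views", {
  td <- tidy(sca3_ens)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1000)
  expect_true(all(c("lineage_id", "status", "terminal_generation") %in%
                    names(td)))
  gl <- glance(sca3_ens)
  expect_equal(nrow(gl), 1)
  expect_identical(gl, glance(sca3_ens$summary))
})
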