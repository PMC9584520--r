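test_that("strain configurations are unique and mode-normalised", {
  cfg <- enumerate_strain_configs()
  expect_equal(nrow(cfg), 84)  # 4 * 3 * (1 + 3*2)
  expect_equal(anyDuplicated(cfg), 0)
  # a specific engineered strain appears exactly once
  hit <- cfg$qs == 1 & cfg$bact == 1 & cfg$mode == 0 & cfg$sens == 0
  expect_equal(sum(hit), 1)
  # the mode flag collapses when no bacteriocin is expressed
  expect_true(all(cfg$mode[cfg$bact == 0] == 0))
})

test_that("unpruned one-strain enumeration matches a brute-force oracle", {
  sp <- enumerate_models(1)
  # oracle: every (sens, qs, bact) config times every regulator/mode
  # assignment of the expressed bacteriocin (none when bactless)
  n_oracle <- 0
  for (sens in 0:3) for (qs in 0:2) for (bact in 0:3)
    n_oracle <- n_oracle + if (bact == 0) 1 else 4
  expect_equal(nrow(sp$models), n_oracle)
})

test_that("pruning enforces the four rules (independent checker)", {
  sp <- get_test_space()
  m <- sp$models
  # written directly from the rules, independently of the package internals
  check_row <- function(r) {
    s <- matrix(r[1:9], ncol = 3, byrow = TRUE)  # sens, qs, bact per strain
    present <- unique(s[, 3][s[, 3] > 0])
    qs_present <- unique(s[, 2][s[, 2] > 0])
    sens_vals <- s[, 1][s[, 1] > 0]
    ok1 <- anyDuplicated(split(s, row(s))) == 0
    ok2 <- all(r[9 + 2 * present - 1] %in% qs_present)
    ok3 <- all(sens_vals %in% present)
    ok4 <- all(present %in% sens_vals)
    ok1 && ok2 && ok3 && ok4
  }
  idx <- seq(1, nrow(m), length.out = 400)
  expect_true(all(vapply(round(idx), function(i) check_row(m[i, ]), logical(1))))
})

test_that("rule violations are removed", {
  sp <- enumerate_models(3)
  pruned <- prune_models(sp)
  key <- function(m) apply(m, 1, paste, collapse = ".")
  pk <- key(pruned$models)
  # a system of three empty strains duplicates configs (rule 1): absent
  expect_false(paste(rep(0L, 15), collapse = ".") %in% pk)
  # no model may reference a regulator that is not expressed (rule 2)
  for (i in round(seq(1, nrow(pruned$models), length.out = 200))) {
    r <- pruned$models[i, ]
    qs_present <- unique(c(r[2], r[5], r[8])); qs_present <- qs_present[qs_present > 0]
    for (z in 1:3) {
      if (any(r[c(3, 6, 9)] == z)) expect_true(r[9 + 2 * z - 1] %in% qs_present)
    }
  }
})

test_that("the calibrated three-strain space is deterministic and idempotent", {
  sp <- get_test_space()
  expect_true(sp$pruned)
  expect_equal(nrow(sp$models), 4163)
  again <- prune_models(enumerate_models(3))
  expect_identical(sp$models, again$models)
  expect_identical(prune_models(sp)$models, sp$models)
  expect_equal(anyDuplicated(apply(sp$models, 1, paste, collapse = ".")), 0)
})

test_that("the focal chaotic topology is present with the expected structure", {
  sp <- get_test_space()
  id <- find_model(sp, focal_structure())
  expect_false(is.na(id))
  mod <- get_model(sp, id)
  props <- model_properties(mod)
  expect_equal(props$n_parts_expressed, 4)
  expect_equal(props$n_qs, 1)
  expect_equal(props$n_bacteriocins, 2)
  expect_equal(props$regulation_summary, "positive")
  expect_equal(props$interaction_summary, "SL+OL")
  st <- build_equation_structure(mod)
  expect_equal(st$n_strains + 1 + st$n_bact + st$n_qs, 7)
  # same canonical structure as the hand-written focal structure
  expect_equal(chaoscope:::.structure_key(st),
               chaoscope:::.structure_key(focal_structure()))
})

test_that("model properties handle bacteriocin-free models", {
  mod <- structure(list(model_id = NA,
                        strains = data.frame(sens = c(0L, 0L, 0L),
                                             qs = c(0L, 1L, 2L),
                                             bact = c(0L, 0L, 0L),
                                             mode = c(0L, 0L, 0L)),
                        regulators = c(0L, 0L, 0L), modes = c(0L, 0L, 0L)),
                   class = "community_model")
  props <- model_properties(mod)
  expect_equal(props$n_bacteriocins, 0)
  expect_equal(props$regulation_summary, "none")
  expect_equal(props$interaction_summary, "none")
})

test_that("state-variable count follows the part content", {
  sp <- get_test_space()
  for (i in c(1, 500, 2000, 4000)) {
    mod <- get_model(sp, i)
    st <- build_equation_structure(mod)
    expect_equal(ncol(st$EB), st$n_bact)
    expect_equal(ncol(st$EA), st$n_qs)
    expect_equal(st$n_strains + 1 + st$n_bact + st$n_qs,
                 3 + 1 + model_properties(mod)$n_bacteriocins +
                   model_properties(mod)$n_qs)
  }
})

test_that("model space round-trips through CSV", {
  sp <- get_test_space()
  f <- tempfile(fileext = ".csv")
  write_model_space(sp, f)
  back <- read_model_space(f)
  expect_identical(back$models, sp$models)
  expect_equal(back$n_strains, sp$n_strains)
  unlink(c(f, paste0(f, ".json")))
})
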