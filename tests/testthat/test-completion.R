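# Completion tests run on small (48^3) phantom pools to keep registration
# fast; the full-scale benchmark lives in the acceptance suite.

local_small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(6, small_phantom_spec(), seed = 301)
      pool <- suppressWarnings(build_pool(cohort, reference_index = 1))
      cache <<- list(cohort = cohort, model = fit_variations(pool))
    }
    cache
  }
})

test_that("clamped subtraction recovers a known removed region exactly", {
  # identity-registration case: work directly in the common space
  p <- generate_phantom(small_phantom_spec())
  dd <- apply_defect(p, defect_spec("sphere", size_fraction = 0.15,
                                    seed = 4))
  missing <- craniossm:::vol_and_not(p, dd$defective)
  expect_identical(missing$data, dd$implant$data)
  # union identity under clamped subtraction
  expect_identical(craniossm:::vol_union(dd$defective, missing)$data, p$data)
})

test_that("template completion of the template itself is a no-op", {
  p <- generate_phantom(small_phantom_spec())
  res <- complete_by_template(p, p)
  expect_lt(sum(res$missing_part$data), 0.02 * sum(p$data))
  expect_gte(dsc(res$completed_original, p), 0.98)
})

test_that("template completion recovers a synthetic defect", {
  p <- generate_phantom(small_phantom_spec())
  dd <- apply_defect(p, defect_spec("sphere", size_fraction = 0.2, seed = 6))
  res <- suppressWarnings(complete_by_template(dd$defective, p))
  expect_gte(dsc(res$missing_part, dd$implant), 0.80)
  expect_gte(dsc(res$completed_original, p), 0.90)
})

test_that("completion results satisfy the partition invariants", {
  fix <- local_small_model()
  p <- fix$cohort[[3]]
  dd <- apply_defect(p, defect_spec("cube", size_fraction = 0.18, seed = 9))
  for (res in list(suppressWarnings(complete_by_template(dd$defective,
                                                         fix$model$reference)),
                   suppressWarnings(complete_by_ssm(dd$defective,
                                                    fix$model)))) {
    expect_equal(sum(res$missing_part$data == 1L &
                       res$warped_defective$data == 1L), 0)
    expect_identical(res$completed_reference$data,
                     craniossm:::vol_union(res$missing_part,
                                           res$warped_defective)$data)
  }
})

test_that("SSM completion of a training member is a near no-op", {
  fix <- local_small_model()
  member <- fix$cohort[[4]]
  res <- suppressWarnings(complete_by_ssm(member, fix$model))
  expect_lt(sum(res$missing_part$data), 0.02 * sum(member$data))
  expect_gte(dsc(res$completed_original, member), 0.97)
})

test_that("SSM completion restores a defective phantom", {
  fix <- local_small_model()
  complete <- fix$cohort[[5]]
  dd <- apply_defect(complete, defect_spec("sphere", size_fraction = 0.2,
                                           seed = 12))
  res <- suppressWarnings(complete_by_ssm(dd$defective, fix$model))
  expect_gte(dsc(res$completed_original, complete), 0.90)
  w <- attr(res, "weights")
  expect_s3_class(w, "shape_weights")
  expect_length(w$lambda_raw, fix$model$n_components)
})

test_that("completion artifacts are written and reloadable", {
  fix <- local_small_model()
  dd <- apply_defect(fix$cohort[[2]], defect_spec("sphere",
                                                  size_fraction = 0.15,
                                                  seed = 2))
  res <- suppressWarnings(complete_by_ssm(dd$defective, fix$model))
  dir <- withr::local_tempdir()
  paths <- write_completion(res, dir, "caseA")
  expect_true(all(file.exists(paths)))
  imp <- read_volume(paths[["implant_raw"]])
  expect_identical(imp$data, res$missing_original$data)
  tr <- read_transform(paths[["transform"]])
  expect_equal(tr$scale, res$transform$scale)
})
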