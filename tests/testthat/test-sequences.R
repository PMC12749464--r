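# Sequence construction, imputation and legality checks.

test_that("assignStates applies the event-year convention", {
  # single ongoing marriage
  r1 <- data.frame(order = 1L, start_year = 1972, end_year = NA_integer_,
                   end_reason = "ongoing")
  s1 <- assignStates(1950, r1)
  expect_equal(unname(s1), c(rep("N", 7), rep("M", 29)))

  # marriage -> divorce -> remarriage
  r2 <- data.frame(order = 1:2, start_year = c(1970, 1985),
                   end_year = c(1980, NA), end_reason = c("divorce", NA))
  s2 <- assignStates(1950, r2)
  expect_equal(unname(s2), c(rep("N", 5), rep("M", 10), rep("D", 5),
                             rep("R", 16)))

  # marriage ending in widowhood
  r3 <- data.frame(order = 1L, start_year = 1980, end_year = 1995,
                   end_reason = "widowhood")
  s3 <- assignStates(1950, r3)
  expect_equal(unname(s3), c(rep("N", 15), rep("M", 15), rep("W", 6)))

  # no records at all
  expect_equal(unname(assignStates(1950, r1[0, ])), rep("N", 36))
  # missing birth year is rejected
  expect_error(assignStates(NA, r1), "birth year")
})

test_that("a closed marriage without an end reason leaves a gap", {
  r <- data.frame(order = 1L, start_year = 1970, end_year = 1980,
                  end_reason = NA_character_)
  s <- assignStates(1950, r)
  expect_equal(unname(s[1:15]), c(rep("N", 5), rep("M", 10)))
  expect_true(all(is.na(s[16:36])))   # from the unexplained end year onward
})

test_that("imputeLOCF fills interior gaps and flags unrepairable persons", {
  # the 1985/1988 example: marriage observed, then a 2-year gap
  s <- rep("M", 36); s[7:8] <- NA    # ages 21-22 missing inside an M spell
  out <- imputeLOCF(s)
  expect_true(out$valid)
  expect_equal(unname(out$states[6:9]), rep("M", 4))
  expect_equal(which(out$imputed), 7:8)

  # fully observed: identity, mask all false
  full <- rep(c("N", "M"), c(10, 26))
  out2 <- imputeLOCF(full)
  expect_identical(unname(out2$states), full)
  expect_false(any(out2$imputed))

  # LOCF by definition: D gap before R
  s3 <- c(rep("N", 10), rep("M", 5), "D", NA, NA, NA, rep("R", 17))
  out3 <- imputeLOCF(s3)
  expect_equal(unname(out3$states[16:20]), c("D", "D", "D", "D", "R"))

  expect_false(imputeLOCF(rep(NA_character_, 36))$valid)
  expect_equal(imputeLOCF(rep(NA_character_, 36))$reason, "all_missing")
  lead <- c(NA, rep("N", 35))
  expect_equal(imputeLOCF(lead)$reason, "leading_missing")
})

test_that("imputeLOCF is idempotent and never alters observed positions", {
  set.seed(42)
  for (rep in 1:20) {
    s <- sample(PARTNER_STATES, 36, replace = TRUE)
    gaps <- sample(2:36, 8)
    sNA <- s; sNA[gaps] <- NA
    out <- imputeLOCF(sNA)
    expect_identical(out$states[-gaps], s[-gaps])        # observed untouched
    again <- imputeLOCF(out$states)
    expect_identical(again$states, out$states)           # idempotent
    expect_false(any(again$imputed))
  }
})

test_that("validateSequence flags illegal life-course transitions", {
  # married -> not married is disallowed
  s <- c(rep("N", 5), rep("M", 11), rep("N", 20))
  v <- validateSequence(s)
  expect_equal(nrow(v), 1)
  expect_equal(v$position, 30)      # age of the M state before the break
  expect_equal(v$from, "M"); expect_equal(v$to, "N")

  # constant N is legal
  expect_equal(nrow(validateSequence(rep("N", 36))), 0)

  # widowhood without any prior marriage is illegal
  s2 <- c(rep("N", 6), rep("W", 30))
  v2 <- validateSequence(s2)
  expect_equal(nrow(v2), 1)
  expect_equal(v2$to, "W")

  expect_error(validateSequence(c(rep("N", 35), "X")), "unknown state")
})

test_that("buildCohort assembles, imputes, validates and logs exclusions", {
  persons <- data.frame(person_id = c("a", "b", "c"),
                        birth_year = c(1950, 1955, 1960),
                        gender = c("male", "female", "female"),
                        stringsAsFactors = FALSE)
  marriages <- data.frame(person_id = c("a", "c"), order = c(1L, 1L),
                          start_year = c(1975, 1981),
                          end_year = c(NA, 1990),
                          end_reason = c("ongoing", "divorce"),
                          stringsAsFactors = FALSE)
  out <- buildCohort(persons, marriages)
  expect_equal(nrow(out$exclusions), 0)
  expect_equal(personIds(out$sequences), c("a", "b", "c"))
  expect_equal(unname(seqStates(out$sequences)["b", ]), rep("N", 36))

  # one all-missing person via the rawStates override
  raw <- matrix(NA_character_, 1, 36,
                dimnames = list("b", paste0("a", SEQ_AGES)))
  out2 <- buildCohort(persons, marriages, rawStates = raw)
  expect_equal(out2$exclusions$person_id, "b")
  expect_equal(out2$exclusions$reason, "all_missing")
  expect_equal(nrow(seqStates(out2$sequences)), 2)

  # overlapping records are excluded with a reason
  mo <- data.frame(person_id = "a", order = 1:2,
                   start_year = c(1975, 1980), end_year = c(1985, NA),
                   end_reason = c("divorce", "ongoing"))
  out3 <- buildCohort(persons[1, ], mo)
  expect_equal(out3$exclusions$reason, "overlapping_records")

  # empty input -> empty outputs
  out4 <- buildCohort(persons[0, ], marriages[0, ])
  expect_equal(nrow(seqStates(out4$sequences)), 0)
  expect_equal(nrow(out4$exclusions), 0)
})

test_that("a gap-injected synthetic cohort is fully repaired by LOCF", {
  sim <- simulateCohort(generatorConfig(n = 500, missingRate = 0.05),
                        seed = 7)
  expect_true(anyNA(sim$rawStates))
  out <- buildCohort(sim$persons, sim$marriages, rawStates = sim$rawStates)
  expect_equal(nrow(out$exclusions), 0)
  expect_equal(nrow(seqStates(out$sequences)), 500)
  # every retained sequence is legal
  viol <- apply(seqStates(out$sequences), 1,
                function(s) nrow(validateSequence(s)))
  expect_true(all(viol == 0))
  # repairable-gap guarantee: imputation reconstructs the latent truth
  expect_identical(seqStates(out$sequences), sim$truth$latentStates)
  expect_true(any(imputedMask(out$sequences)))
})

test_that("record-derived sequences reproduce the latent state matrix", {
  sim <- simulateCohort(generatorConfig(n = 300, missingRate = 0), seed = 3)
  out <- buildCohort(sim$persons, sim$marriages)
  expect_equal(nrow(out$exclusions), 0)
  expect_identical(seqStates(out$sequences), sim$truth$latentStates)
  expect_false(any(imputedMask(out$sequences)))
})

test_that("stateDistribution columns are proper proportions", {
  allN <- seqSetFromStrings(strrep("N", 36))
  dN <- stateDistribution(allN)
  expect_equal(unname(dN["N", ]), rep(1, 36))
  expect_equal(unname(colSums(dN)), rep(1, 36))

  two <- seqSetFromStrings(c(strrep("N", 36), strrep("M", 36)))
  d2 <- stateDistribution(two)
  expect_equal(unname(d2["N", ]), rep(0.5, 36))
  expect_equal(unname(d2["M", ]), rep(0.5, 36))

  sim <- simulateCohort(generatorConfig(n = 400), seed = 9)
  seqs <- new("StateSequenceSet", states = sim$truth$latentStates,
              imputed = sim$truth$latentStates == "ZZ")
  d <- stateDistribution(seqs)
  expect_true(all(abs(colSums(d) - 1) < 1e-12))
  # stratified tables: one per gender, each summing to 1
  dg <- stateDistribution(seqs, by = sim$persons$gender)
  expect_setequal(names(dg), c("male", "female"))
  expect_true(all(abs(colSums(dg$female) - 1) < 1e-12))
})

test_that("sequence and table files round-trip losslessly", {
  sim <- simulateCohort(generatorConfig(n = 40), seed = 2)
  out <- buildCohort(sim$persons, sim$marriages)
  f <- tempfile(fileext = ".csv")
  writeSequences(out$sequences, f)
  back <- readSequences(f)
  expect_identical(seqStates(back), seqStates(out$sequences))
  unlink(f)
})
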