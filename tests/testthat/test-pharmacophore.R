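# Model-building fixtures: 24 complexes sharing a donor, an acceptor and
# two stacked aromatic rings (receptor coordinates jittered per complex).
shared_complexes <- function(n = 24, channels = c(3, 4, 1, 1)) {
  lapply(seq_len(n), function(s) {
    cx <- mk_complex(channels, sigma = 0.15, seed = s)
    list(receptor = cx$receptor, ligand = cx$ligand)
  })
}

test_that("24 complexes sharing four planted features give a 4-feature model", {
  model <- build_pharmacophore(shared_complexes())
  expect_s3_class(model, "pharmacophore_model")
  expect_equal(nrow(model$features), 4L)
  expect_setequal(model$features$kind,
                  c("donor", "acceptor", "aromatic", "aromatic"))
  expect_true(all(model$features$occupancy >= model$retention))
})

test_that("feature retention follows occupancy arithmetic at the 50% threshold", {
  mixed <- function(k) {
    # k complexes carry a fifth feature (an extra protein-donor contact)
    lapply(1:24, function(s) {
      ch <- if (s <= k) c(3, 4, 1, 1, 3) else c(3, 4, 1, 1)
      cx <- mk_complex(ch, sigma = 0.15, seed = s)
      list(receptor = cx$receptor, ligand = cx$ligand)
    })
  }
  # 13/24 = 54% occupancy: retained
  expect_equal(nrow(build_pharmacophore(mixed(13))$features), 5L)
  # 11/24 = 46% occupancy: dropped
  expect_equal(nrow(build_pharmacophore(mixed(11))$features), 4L)
})

test_that("raising retention never adds features", {
  cxs <- shared_complexes(8)
  cxs <- c(cxs, lapply(1:3, function(s) {
    cx <- mk_complex(c(3, 4, 1, 1, 3), sigma = 0.15, seed = 100 + s)
    list(receptor = cx$receptor, ligand = cx$ligand)
  }))
  lo <- build_pharmacophore(cxs, retention = 0.2)
  hi <- build_pharmacophore(cxs, retention = 0.9)
  expect_lte(nrow(hi$features), nrow(lo$features))
  key <- function(m) paste(m$features$kind, round(m$features$x, 1),
                           round(m$features$y, 1))
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("model building is independent of complex input order", {
  cxs <- shared_complexes(10)
  m1 <- build_pharmacophore(cxs)
  m2 <- build_pharmacophore(rev(cxs))
  expect_equal(m1$features, m2$features, tolerance = 1e-12)
})

test_that("the reference ligand matches a model built from its own complexes", {
  model <- build_pharmacophore(shared_complexes())
  lig <- mk_complex(c(3, 4, 1, 1))$ligand
  res <- pharm_matches(model, lig)
  expect_true(res$match)
  expect_true(all(res$report$satisfied))
})

test_that("a displaced pose fails with all features unmet", {
  model <- build_pharmacophore(shared_complexes())
  far <- translate(mk_complex(c(3, 4, 1, 1))$ligand, c(20, 0, 0))
  res <- pharm_matches(model, far)
  expect_false(res$match)
  expect_false(any(res$report$satisfied))
})

test_that("a pose meeting 3 of 4 features fails and the report names the gap", {
  model <- build_pharmacophore(shared_complexes())
  lig <- mk_complex(c(3, 4, 1, 1))$ligand
  # disable the donor: turn the amine nitrogen into a carbon
  amine_n <- which(lig$atoms$elem == "N")
  lig$atoms$elem[amine_n] <- "C"
  res <- pharm_matches(model, lig)
  expect_false(res$match)
  expect_equal(sum(res$report$satisfied), 3L)
  expect_equal(res$report$kind[!res$report$satisfied], "donor")
})

test_that("loosening tolerance never turns a pass into a fail", {
  model <- build_pharmacophore(shared_complexes())
  set.seed(4)
  lig <- mk_complex(c(3, 4, 1, 1))$ligand
  lig$atoms$x <- lig$atoms$x + rnorm(nrow(lig$atoms), 0, 0.3)
  for (tol in c(0.5, 1.0, 2.0)) {
    if (pharm_matches(model, lig, tolerance = tol)$match)
      expect_true(pharm_matches(model, lig, tolerance = tol + 1)$match)
  }
})

test_that("models serialize to JSON and back", {
  model <- build_pharmacophore(shared_complexes(6))
  f <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore(model, f)
  back <- read_pharmacophore(f)
  expect_equal(back$features$kind, model$features$kind)
  expect_equal(back$features$x, model$features$x, tolerance = 1e-9)
  expect_equal(back$retention, model$retention)
})

test_that("an empty complex list is an error", {
  expect_error(build_pharmacophore(list()), "empty")
})
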