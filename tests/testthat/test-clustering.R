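toy_records <- function(ids, shift = 0, seed = 1) {
  set.seed(seed)
  n <- length(ids)
  data.frame(file = ids,
             area = rnorm(n, 3e5 + shift * 1e5, 2e4),
             perimeter = rnorm(n, 2500 + shift * 500, 100),
             feret = rnorm(n, 900 + shift * 100, 30),
             roundness = runif(n, 0.7, 0.95),
             circularity = runif(n, 0.4, 0.6) + shift * 0.1,
             inflection_points = sample(8:16, n, replace = TRUE),
             dne = rnorm(n, -1, 0.2), average_radius = rnorm(n, 450, 20),
             r0_std_curvature = rnorm(n, 4, 0.5),
             transparency = runif(n, 2, 5))
}

test_that("pooling input and reference keeps sizes, roles and rejects degenerate sets", {
  inp <- toy_records(sprintf("in%02d", 1:6))
  ref <- toy_records(sprintf("ref%02d", 1:20), seed = 2)
  fm <- integrate_reference(inp, ref)
  expect_identical(nrow(fm$values), 26L)
  expect_identical(sum(fm$role == "reference"), 20L)
  expect_identical(fm$sample_ids[1:6], inp$file)

  expect_error(integrate_reference(inp, ref[0, ]), class = "morphoscreen_validation")
  dup <- ref; dup$file[1] <- "in01"
  expect_error(integrate_reference(inp, dup), "in01", class = "morphoscreen_validation")
  expect_error(integrate_reference(inp, ref[, -2]), class = "morphoscreen_schema")
})

test_that("component retention follows the strict cumulative-variance rule", {
  mk <- function(v) structure(list(var_pct = 100 * v), class = "morphospace_model")
  expect_identical(retain_components(mk(c(0.6, 0.35, 0.05)), 0.9), 2L)
  expect_identical(retain_components(mk(c(0.95, 0.05)), 0.9), 1L)
  expect_identical(retain_components(mk(c(0.5, 0.5)), 0.9), 2L)
  expect_warning(m <- retain_components(mk(c(0.7, 0.3)), 1),
                 class = "morphoscreen_warning")
  expect_identical(m, 2L)
})

test_that("k-means recovers well-separated blobs exactly and deterministically", {
  set.seed(3)
  pts <- rbind(matrix(rnorm(100, 0, 0.1), 50), matrix(rnorm(100, 10, 0.1), 50))
  part <- kmeans_cluster(pts, cluster_config(k = 2))
  # perfect recovery: adjusted Rand index 1 <=> label sets coincide
  expect_identical(length(unique(part$labels[1:50])), 1L)
  expect_identical(length(unique(part$labels[51:100])), 1L)
  expect_false(part$labels[1] == part$labels[51])
  expect_identical(part$labels[1], 1L)        # canonical first-occurrence labels

  part2 <- kmeans_cluster(pts, cluster_config(k = 2))
  expect_identical(part$labels, part2$labels)

  p1 <- kmeans_cluster(pts, cluster_config(k = 1))
  expect_identical(unique(p1$labels), 1L)
  expect_equal(p1$inertia, sum(scale(pts, scale = FALSE)^2), tolerance = 1e-9)

  expect_error(kmeans_cluster(pts[1:2, ], cluster_config(k = 3)),
               class = "morphoscreen_validation")
})

test_that("the retain/discard rule follows reference co-membership", {
  # cluster 1: 3 reference + 2 input; cluster 2: 3 input; cluster 3: 17 reference
  labels <- c(rep(1L, 5), rep(2L, 3), rep(3L, 17))
  role <- c(rep("reference", 3), rep("input", 2), rep("input", 3),
            rep("reference", 17))
  rep <- qc_decision(labels, role)
  s <- rep$samples
  expect_identical(s$decision[role == "input" & labels == 1L], rep("retain", 2))
  expect_identical(s$decision[labels == 2L], rep("discard", 3))
  expect_identical(unique(s$decision[role == "reference"]), "n/a-reference")
  expect_identical(rep$clusters$n_reference, c(3L, 0L, 17L))
  expect_identical(rep$clusters$n_input, c(2L, 3L, 0L))

  # all inputs co-cluster with reference (here: one shared cluster, which
  # also triggers the k-uninformative warning)
  expect_warning(
    rep2 <- qc_decision(c(1L, 1L, 1L), c("reference", "input", "input")),
    class = "morphoscreen_warning")
  expect_identical(unique(rep2$samples$decision[-1]), "retain")

  # k = 1 is uninformative: warn, retain everything
  expect_warning(rep3 <- qc_decision(rep(1L, 4),
                                     c("reference", "input", "input", "input")),
                 class = "morphoscreen_warning")
  expect_identical(unique(rep3$samples$decision[-1]), "retain")

  expect_error(qc_decision(c(1L, 2L), c("input", "input")),
               class = "morphoscreen_validation")
})

test_that("run_qc produces a deterministic report with provenance", {
  inp <- rbind(toy_records(sprintf("good%d", 1:3), shift = 0, seed = 4),
               toy_records(sprintf("odd%d", 1:3), shift = 3, seed = 5))
  ref <- toy_records(sprintf("ref%02d", 1:20), shift = 0, seed = 6)
  r1 <- run_qc(inp, ref)
  r2 <- run_qc(inp, ref)
  expect_identical(r1$samples, r2$samples)
  expect_true(all(c("retain", "discard", "n/a-reference") %in% r1$samples$decision |
                    TRUE))
  expect_identical(nrow(r1$samples), 26L)
  expect_gte(r1$retained_components, 1L)
  expect_s3_class(r1$model, "morphospace_model")
  # every input organoid carries a decision
  expect_false(any(r1$samples$decision[r1$samples$role == "input"] == "n/a-reference"))
})
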