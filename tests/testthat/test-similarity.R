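test_that("expression similarity matches hand-computed Pearson values and clip policy", {
  ep <- expression_profiles(rbind(a = c(1, 5, 2), b = c(1, 5, 2),
                                  c = c(1, 2, 3), d = c(3, 2, 1),
                                  e = c(1, 2, 4)),
                            tissue_names = c("t1", "t2", "t3"))
  ES <- expression_similarity(ep, c("a", "b", "c", "d", "e"))
  expect_equal(ES$S["a", "b"], 1)
  expect_equal(ES$S["c", "d"], 0)            # Pearson -1, clipped
  expect_equal(ES$S["c", "e"], 9 / sqrt(84)) # = 0.9819805
  ES2 <- expression_similarity(ep, c("a", "b", "c", "d", "e"), negative = "affine")
  expect_equal(ES2$S["c", "d"], 0)           # (-1 + 1)/2
  expect_equal(ES2$S["c", "e"], (9 / sqrt(84) + 1) / 2)
})

test_that("uncovered and zero-variance miRNAs get zero rows and covered = FALSE", {
  ep <- expression_profiles(rbind(a = c(1, 2, 3), z = c(4, 4, 4)),
                            tissue_names = paste0("t", 1:3))
  expect_warning(expression_similarity(ep, c("a", "z", "missing")),
                 "zero-variance")
  ES <- suppressWarnings(expression_similarity(ep, c("a", "z", "missing")))
  expect_equal(ES$covered, c(TRUE, FALSE, FALSE))
  expect_equal(ES$S["z", ], c(a = 0, z = 0, missing = 0))
})

test_that("semantic contributions follow the max-over-children decay recursion", {
  mf <- mesh_forest(list(single = "C01",
                         chain = "C01.252",
                         deep = c("C01.252.410", "C01.252")))
  sc1 <- semantic_contributions(mf, "single")
  expect_equal(sc1$contributions, c(C01 = 1))
  expect_equal(sc1$aggregate, 1)

  sc2 <- semantic_contributions(mf, "chain", delta = 0.5)
  expect_equal(sc2$contributions[["C01"]], 0.5)
  expect_equal(sc2$aggregate, 1.5)

  # C01.252 reachable as own code (1) and as parent of C01.252.410 (0.5):
  # max rule keeps 1; C01 then gets 0.5, the shorter of 0.5 and 0.25
  sc3 <- semantic_contributions(mf, "deep", delta = 0.5)
  expect_equal(sc3$contributions[["C01.252"]], 1)
  expect_equal(sc3$contributions[["C01"]], 0.5)

  expect_error(semantic_contributions(mf, "nope"), "not in MeSH forest")
})

test_that("contributions equal delta^depth on pure chains (path oracle)", {
  for (depth in 2:5) {
    code <- paste(c("C01", sprintf("%03d", seq_len(depth - 1))), collapse = ".")
    mf <- mesh_forest(setNames(list(code), "d"))
    sc <- semantic_contributions(mf, "d", delta = 0.4)
    # oracle: a chain has a unique root-to-node path; C = delta^distance
    dist <- depth - lengths(strsplit(names(sc$contributions), ".", fixed = TRUE))
    expect_equal(unname(sc$contributions), 0.4^dist)
  }
})

test_that("disease semantic similarity reproduces the two-code worked example", {
  mf <- mesh_forest(list(d1 = "C01.252", d2 = "C01.539", d3 = "F01.100"))
  SS <- disease_semantic_similarity(mf, c("d1", "d2", "d3", "unmapped"))
  expect_equal(SS$S["d1", "d1"], 1)
  expect_equal(SS$S["d1", "d2"], 1 / 3)  # shared C01: (0.5+0.5)/(1.5+1.5)
  expect_equal(SS$S["d1", "d3"], 0)      # disjoint DAGs
  expect_equal(SS$covered, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("GIP kernel matches hand-computed values and scales with gamma_prime", {
  ds <- association_dataset(c("d1", "d2"), c("m1", "m2"),
                            rbind(c(1, 1), c(2, 2)))
  KD <- gip_kernel(ds, "disease")
  expect_equal(KD$S["d1", "d2"], exp(-2))  # gamma_d = 1/mean(1,1) = 1
  expect_equal(diag(KD$S), c(d1 = 1, d2 = 1))
  KD2 <- gip_kernel(ds, "disease", gamma_prime = 2)
  expect_equal(KD2$S["d1", "d2"], exp(-4))

  empty <- association_dataset("d1", "m1", matrix(0, 1, 1))
  expect_error(gip_kernel(empty, "disease"), "bandwidth undefined")
})

test_that("GIP kernel agrees with a brute-force double loop on random matrices", {
  set.seed(42)
  for (rep in 1:3) {
    U <- matrix(rbinom(150, 1, 0.3), 10, 15)
    if (all(U == 0)) U[1, 1] <- 1L
    ds <- association_dataset(paste0("d", 1:10), paste0("m", 1:15), U)
    expect_equal(unname(gip_kernel(ds, "disease")$S), gip_brute(U, "disease"),
                 tolerance = 1e-12)
    expect_equal(unname(gip_kernel(ds, "mirna")$S), gip_brute(U, "mirna"),
                 tolerance = 1e-12)
  }
})

test_that("integrated similarities average where covered and fall back to the kernel", {
  nm <- c("m1", "m2", "m3")
  ES <- similarity_matrix(rbind(c(1, .8, 0), c(.8, 1, 0), c(0, 0, 0)), nm,
                          covered = c(TRUE, TRUE, FALSE), check = FALSE)
  KM <- similarity_matrix(rbind(c(1, .4, .3), c(.4, 1, .2), c(.3, .2, 1)), nm)
  S_m <- integrate_mirna_similarity(ES, KM)
  expect_equal(S_m$S["m1", "m2"], 0.6)        # both covered: mean
  expect_equal(S_m$S["m1", "m3"], 0.3)        # m3 uncovered: pure KM
  S_same <- integrate_mirna_similarity(ES, ES)
  expect_equal(S_same$S[1:2, 1:2], ES$S[1:2, 1:2])

  SS <- similarity_matrix(rbind(c(1, .7), c(.7, 1)), c("d1", "d2"),
                          covered = c(TRUE, TRUE))
  KD <- similarity_matrix(rbind(c(1, .2), c(.2, 1)), c("d1", "d2"))
  expect_equal(integrate_disease_similarity(SS, KD)$S["d1", "d2"], 0.7)
  SS$covered[2] <- FALSE
  expect_equal(integrate_disease_similarity(SS, KD)$S["d1", "d2"], 0.2)
  expect_equal(diag(integrate_disease_similarity(SS, KD)$S),
               c(d1 = 1, d2 = 1))

  expect_error(integrate_mirna_similarity(ES, similarity_matrix(diag(2), c("a", "b"))),
               "different miRNA lists")
})

test_that("every similarity in the stack is symmetric, bounded and unit-diagonal", {
  syn <- simulate_mda(n_diseases = 15, n_mirnas = 25, density = 0.08, seed = 9)
  sims <- fmsm_similarities(syn$associations, syn$expression, syn$mesh)
  for (nmx in c("ES", "SS", "KD", "KM", "S_m", "S_d")) {
    S <- sims[[nmx]]$S
    expect_lte(max(abs(S - t(S))), 1e-9)
    expect_gte(min(S), -1e-9)
    expect_lte(max(S), 1 + 1e-9)
    cov <- sims[[nmx]]$covered
    if (any(cov)) expect_equal(unname(diag(S)[cov]), rep(1, sum(cov)))
  }
})

test_that("similarity matrices survive a TSV round trip", {
  syn <- simulate_mda(n_diseases = 8, n_mirnas = 12, seed = 2)
  KM <- gip_kernel(syn$associations, "mirna")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(KM, f)
  back <- read_similarity(f)
  expect_equal(back$names, KM$names)
  expect_equal(unname(back$S), unname(KM$S), tolerance = 1e-12)
})
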