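test_that("generation is a pure function of seed and respects n_domains", {
  a <- gen_protein(seed = 42)
  b <- gen_protein(seed = 42)
  expect_identical(a$parent$residues, b$parent$residues)
  expect_identical(a$domain_map, b$domain_map)

  one <- gen_protein(n_domains = 1, seed = 1)
  expect_equal(one$domain_map$label, "rigid-core")
  expect_equal(nrow(one$linkers), 0L)
  expect_false(one$flexible)

  three <- gen_protein(n_domains = 3, seed = 2)
  expect_equal(sum(three$domain_map$label == "rigid-core"), 3L)
  expect_equal(sum(three$domain_map$label == "flexible-linker"), 2L)
  # intervals tile the chain
  expect_equal(three$domain_map$ref_end[nrow(three$domain_map)],
               nchar(three$parent$residues))
})

test_that("linkers are acidic-enriched relative to cores", {
  de_frac <- function(s) {
    ch <- strsplit(s, "")[[1]]
    mean(ch %in% c("D", "E"))
  }
  core_frac <- c(); link_frac <- c()
  for (seed in 1:100) {
    tr <- gen_protein(n_domains = 2, seed = seed)
    dm <- tr$domain_map
    seqs <- substring(tr$parent$residues, dm$ref_start, dm$ref_end)
    core_frac <- c(core_frac, sapply(seqs[dm$label == "rigid-core"], de_frac))
    link_frac <- c(link_frac, sapply(seqs[dm$label == "flexible-linker"], de_frac))
  }
  expect_gt(mean(link_frac), mean(core_frac))
  expect_gt(min(link_frac), 0.1)
})

test_that("a noiseless digest releases the cores bounded by linker sites", {
  tr <- gen_protein(n_domains = 2, seed = 7)
  obs <- simulate_digest(tr, mass_sd = 0)
  last <- obs[obs$time_point == max(obs$time_point), ]
  expect_true(all(last$persistent))

  # persistent fragments containing a core start/end at accessible linker
  # sites immediately adjacent to the core edges
  dm <- tr$domain_map
  cores <- dm[dm$label == "rigid-core", ]
  for (i in seq_len(nrow(cores))) {
    hit <- last[last$true_start <= cores$ref_start[i] &
                  last$true_end >= cores$ref_end[i], ]
    expect_equal(nrow(hit), 1L)
    expect_lte(abs(hit$true_start - cores$ref_start[i]), 2L)
    expect_lte(abs(hit$true_end - cores$ref_end[i]), 2L)
    # zero noise: the observed mass is exactly the theoretical mass
    expect_equal(hit$observed_mass,
                 peptide_mass(substr(tr$construct$chain, hit$true_start,
                                     hit$true_end)),
                 tolerance = 1e-12)
  }

  # the undigested chain shows up early but is not persistent
  first <- obs[obs$time_point == min(obs$time_point), ]
  expect_true(any(first$true_start == 1 &
                    first$true_end == nchar(tr$parent$residues)))
  expect_false(any(first$persistent[first$true_start == 1 &
                                      first$true_end == nchar(tr$parent$residues)]))
})

test_that("slow sites fire 100-300x later than fast sites", {
  # hand-built truth: two Glu/Asp-free cores joined by a long linker whose
  # only interior cleavage point is a single slow-class Asp site
  core <- strrep("KVLIMFYWHQ", 3)                       # 30 residues
  linker <- paste0("ESSS", strrep("T", 30), "D", strrep("T", 30), "ESE")
  chain <- paste0(core, linker, core)
  l1 <- nchar(core) + 1L
  l2 <- nchar(core) + nchar(linker)
  d_pos <- nchar(core) + 4L + 30L + 1L                  # the Asp P1 position
  tr <- structure(list(
    parent = tibble::tibble(id = "manual", residues = chain,
                            description = "manual"),
    construct = toy_construct(chain, id = "manual"),
    domain_map = tibble::tibble(
      ref_start = c(1L, l1, l2 + 1L),
      ref_end = c(nchar(core), l2, nchar(chain)),
      label = c("rigid-core", "flexible-linker", "rigid-core")),
    linkers = tibble::tibble(ref_start = l1, ref_end = l2),
    mass_sd = 0, ve_sd = 0.01, sls_sd = 0.03,
    flexible = TRUE, shape_ratio = 2, seed = 1
  ), class = "synthetic_truth")

  obs <- simulate_digest(tr, mass_sd = 0,
                         time_points = c(1, 24, 1000, 2000))
  at <- function(t) obs[obs$time_point == t, ]
  # at 24 h only fast (Glu) sites have fired: the linker middle is one piece
  expect_true(any(at(24)$true_start == l1 + 1L &
                    at(24)$true_end == l2 - 2L))
  expect_false(any(at(24)$true_end == d_pos))
  # with k_fast = 1/h and a 200x slower Asp class, the Asp bond has fired by
  # 1000 h and splits the middle piece
  expect_true(any(at(1000)$true_end == d_pos))
  expect_true(any(at(1000)$true_start == d_pos + 1L))
  expect_false(any(at(1000)$true_start == l1 + 1L &
                     at(1000)$true_end == l2 - 2L))
  # linker-only pieces never persist: the end point holds only core bands
  expect_true(all(at(2000)$true_start <= l1 | at(2000)$true_start > l2 |
                    at(2000)$true_end > l2))
  expect_true(all(at(2000)$persistent))
})

test_that("fragment inference recovers simulated truth at MALDI-scale noise", {
  hits <- 0L; total <- 0L
  for (seed in 1:200) {
    tr <- gen_protein(n_domains = 2, seed = seed)
    obs <- simulate_digest(tr, mass_sd = 0.003)
    last <- obs[obs$time_point == max(obs$time_point) & obs$persistent, ]
    calls <- infer_fragments(last, tr$construct)
    total <- total + nrow(calls)
    hits <- hits + sum(calls$ref_start == last$true_start &
                         calls$ref_end == last$true_end)
  }
  expect_gte(hits / total, 0.99)
})

test_that("GPC/SLS simulation reproduces shape classes and scales", {
  cal <- fit_calibration(tibble::tibble(
    name = c("a", "b", "c", "d"), mw_da = c(66430, 29000, 12384, 6511),
    ve_ml = c(1.62, 1.89, 2.17, 2.38)))
  rigid <- gen_protein(n_domains = 1, seed = 11)
  flex <- gen_protein(n_domains = 2, seed = 12)
  m <- simulate_gpc_sls(list(rigid, flex), cal, seed = 1,
                        sls_sd = 0, ve_sd = 0)
  expect_equal(classify_shape(m$shape_ratio[1]), "rigid-compact")
  expect_equal(classify_shape(m$shape_ratio[2]), "flexible-extended")
  # zero noise: MW_SLS equals the true mass
  expect_equal(m$mw_sls_kda, m$mw_th_kda, tolerance = 1e-12)

  # end-to-end shape-class recovery with noise over many seeds
  ok <- 0L
  for (seed in 1:100) {
    tr <- gen_protein(n_domains = if (seed %% 2) 1 else 2, seed = seed)
    mm <- simulate_gpc_sls(tr, cal, seed = seed)
    want <- if (tr$flexible) "flexible-extended" else "rigid-compact"
    ok <- ok + (classify_shape(mm$shape_ratio) == want)
  }
  expect_gte(ok / 100, 0.95)
})
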