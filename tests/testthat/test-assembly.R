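test_that("persistent fragments merge into maximal rigid cores", {
  labels <- tibble::tibble(
    ref_start = c(18, 18, 286, 295, 388),
    ref_end = c(192, 227, 524, 510, 524),
    persistent = TRUE
  )
  cores <- rigid_cores(labels)
  expect_equal(cores$ref_start, c(18L, 286L))
  expect_equal(cores$ref_end, c(227L, 524L))

  one <- rigid_cores(tibble::tibble(ref_start = 5, ref_end = 50))
  expect_equal(one$ref_start, 5L)
  expect_equal(one$ref_end, 50L)

  expect_equal(nrow(rigid_cores(tibble::tibble(
    ref_start = integer(), ref_end = integer()))), 0L)
})

test_that("interval merging equals the brute-force union on random sets", {
  withr::with_seed(19, {
    for (i in 1:40) {
      n <- sample(1:12, 1)
      s <- sample(1:300, n, replace = TRUE)
      e <- s + sample(0:80, n, replace = TRUE)
      got <- rigid_cores(tibble::tibble(ref_start = s, ref_end = e))
      want <- oracle_merge(s, e)
      expect_equal(got$ref_start, want$ref_start)
      expect_equal(got$ref_end, want$ref_end)
    }
  })
})

test_that("cores never shrink when persistent fragments are added", {
  withr::with_seed(23, {
    base <- tibble::tibble(ref_start = c(10, 100), ref_end = c(50, 160))
    cores0 <- rigid_cores(base)
    for (i in 1:15) {
      extra <- tibble::tibble(ref_start = sample(1:200, 1))
      extra$ref_end <- extra$ref_start + sample(0:60, 1)
      cores1 <- rigid_cores(dplyr::bind_rows(base, extra))
      # every originally-core position is still inside some core
      for (j in seq_len(nrow(cores0))) {
        pos <- c(cores0$ref_start[j], cores0$ref_end[j])
        expect_true(all(sapply(pos, function(p) {
          any(p >= cores1$ref_start & p <= cores1$ref_end)
        })))
      }
    }
  })
})

test_that("gaps become linkers only where cleavage was observed", {
  cores <- tibble::tibble(ref_start = c(18, 286), ref_end = c(227, 524))
  map <- classify_map(cores, span = c(18, 624),
                      cut_bonds = c(227L, 285L, 524L))
  expect_equal(map$ref_start, c(18L, 228L, 286L, 525L))
  expect_equal(map$ref_end, c(227L, 285L, 524L, 624L))
  expect_equal(map$label, c("rigid-core", "flexible-linker", "rigid-core",
                            "flexible-linker"))

  # without evidence the gaps stay undetermined
  blank <- classify_map(cores, span = c(18, 624))
  expect_equal(blank$label[c(2, 4)], c("undetermined", "undetermined"))

  # one core spanning the whole span leaves no linkers
  full <- classify_map(tibble::tibble(ref_start = 1, ref_end = 100),
                       span = c(1, 100))
  expect_equal(nrow(full), 1L)
  expect_equal(full$label, "rigid-core")

  expect_error(
    classify_map(tibble::tibble(ref_start = c(1, 5), ref_end = c(10, 20)),
                 span = c(1, 30)),
    class = "domainmapr_schema_error")
})

test_that("maps tile the analyzed span exactly", {
  withr::with_seed(29, {
    for (i in 1:20) {
      n <- sample(1:5, 1)
      s <- sort(sample(seq(10, 400, by = 25), n))
      e <- s + sample(5:20, n, replace = TRUE)
      cores <- rigid_cores(tibble::tibble(ref_start = s, ref_end = e))
      span <- c(1L, 450L)
      map <- classify_map(cores, span)
      expect_equal(map$ref_start[1], span[1])
      expect_equal(map$ref_end[nrow(map)], span[2])
      expect_true(all(map$ref_start[-1] == map$ref_end[-nrow(map)] + 1L))
    }
  })
})

test_that("assembly is idempotent and reproduces the published architecture", {
  cons <- app_constructs()
  calls <- infer_fragments(app_observations(), cons)
  map <- assemble_domains(calls, constructs = cons)
  expect_s3_class(map, "domain_map")
  expect_equal(attr(map, "span"), c(18L, 624L))
  expect_equal(map$label, c("rigid-core", "flexible-linker", "rigid-core",
                            "flexible-linker"))

  # feeding the map's own cores back in changes nothing
  again <- rigid_cores(tibble::tibble(
    ref_start = map$ref_start[map$label == "rigid-core"],
    ref_end = map$ref_end[map$label == "rigid-core"]))
  expect_equal(again$ref_start, map$ref_start[map$label == "rigid-core"])
  expect_equal(again$ref_end, map$ref_end[map$label == "rigid-core"])
})

test_that("nested persistent fragments mark partial-flexibility subdomains", {
  cons <- app_constructs()
  calls <- infer_fragments(app_observations(), cons)
  subs <- attr(assemble_domains(calls, constructs = cons), "subdomains")
  # the extension-domain inference: a short and a long stable species share
  # their N-terminus, so the differential C-terminal segment is partially
  # flexible
  expect_true(any(subs$ref_start == 193 & subs$ref_end == 227 &
                    subs$side == "C-terminal"))
  # the same logic on shared C-termini flags the trimmed N-terminal segment
  expect_true(any(subs$ref_start == 295 & subs$ref_end == 385 &
                    subs$side == "N-terminal"))
})

test_that("user annotation overrides relabel computed intervals", {
  cons <- app_constructs()
  calls <- infer_fragments(app_observations(), cons)
  ov <- tibble::tibble(ref_start = 525L, ref_end = 624L,
                       label = "undetermined")
  map <- assemble_domains(calls, constructs = cons, overrides = ov)
  expect_equal(map$label[map$ref_start == 525], "undetermined")
})
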