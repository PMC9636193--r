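test_that("feature ids follow the M<mz>T<rt> convention with collision suffixes", {
  expect_equal(make_feature_id(153.0398, 555.4), "M153T555")
  expect_equal(make_feature_id(285.0810, 555.0), "M285T555")
  expect_equal(make_feature_id(100.5, 0), "M100T0") # round-half-even
  expect_equal(make_feature_id(c(153.0398, 153.2, 153.4), c(555, 555, 555)),
               c("M153T555", "M153T555_1", "M153T555_2"))
  expect_error(make_feature_id(Inf, 10), "non-finite")
})

test_that("feature tables load across dialects with RT normalized to seconds", {
  generic <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,rt,s1,s2", "153.0398,555.4,100,200", "285.081,555,50,60"),
             generic)
  ft <- read_feature_table(generic)
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$feature_id, c("M153T555", "M285T555"))
  expect_equal(ft$intensities[[1]], c(s1 = 100, s2 = 200))

  msdial <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Average Mz\tAverage Rt(min)\ts1", "153.0398\t9.25\t100"), msdial)
  ft2 <- read_feature_table(msdial, dialect = "msdial")
  expect_equal(ft2$rt, 555) # minutes converted

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rt,s1", "555,100"), bad)
  expect_error(read_feature_table(bad), "m/z column")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,mz,rt,s1", "F1,100,10,5", "F1,200,20,6"), dup)
  expect_error(read_feature_table(dup), "duplicated feature ids.*F1")
})

test_that("MGF and MSP spectra parse, clean and link", {
  mgf <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=M285T555", "PEPMASS=285.0810",
               "RTINSECONDS=555", "153.0398 100", "135.0301 40",
               "110.0351 20", "END IONS"), mgf)
  sp <- read_spectra(mgf)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$precursor_mz, 285.0810)
  expect_equal(nrow(sp$spectrum[[1]]$peaks), 3L)
  expect_equal(sp$spectrum[[1]]$peaks$mz, sort(sp$spectrum[[1]]$peaks$mz))

  msp <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("NAME: inosine", "PRECURSORMZ: 269.0880", "Num Peaks: 2",
               "137.0458 100", "110.0351 30", ""), msp)
  sp2 <- read_spectra(msp)
  expect_equal(nrow(sp2), 1L)
  expect_equal(nrow(sp2$spectrum[[1]]$peaks), 2L)

  wrong <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("NAME: x", "Num Peaks: 3", "100 1"), wrong)
  expect_error(read_spectra(wrong), "record 1")

  empty <- withr::local_tempfile(fileext = ".mgf")
  writeLines(character(0), empty)
  expect_equal(nrow(read_spectra(empty)), 0L)

  ft <- make_features(mz = c(285.0810, 500.1), rt = c(556, 100),
                      intensities = rep(list(c(s1 = 1)), 2))
  linked <- link_spectra(ft, sp)
  expect_false(is.null(linked$ms2[[1]]))
  expect_null(linked$ms2[[2]])
})

test_that("network export round-trips and rejects dangling edges", {
  nodes <- tibble::tibble(id = c("a", "b", "c"), kind = c("x", "y", "z"))
  edges <- tibble::tibble(from = c("a", "b"), to = c("b", "c"), w = c(1.5, 2))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(nodes, edges, path)
  back <- read_network(path)
  expect_setequal(back$nodes$id, nodes$id)
  expect_equal(dplyr::arrange(back$nodes, .data$id)$kind,
               dplyr::arrange(nodes, .data$id)$kind)
  expect_setequal(paste(back$edges$from, back$edges$to),
                  paste(edges$from, edges$to))
  expect_equal(sort(back$edges$w), sort(edges$w))

  prefix <- withr::local_tempfile()
  write_network(nodes, edges, prefix, format = "node_edge_tables")
  back2 <- read_network(prefix, format = "node_edge_tables")
  expect_equal(back2$nodes, nodes)
  expect_equal(back2$edges, edges)

  empty_path <- withr::local_tempfile(fileext = ".graphml")
  write_network(nodes[0, ], edges[0, ], empty_path)
  expect_equal(nrow(read_network(empty_path)$nodes), 0L)

  expect_error(write_network(nodes, tibble::tibble(from = "a", to = "zz"),
                             path), "missing node")
})

test_that("MGF writer round-trips spectra written from a feature table", {
  s <- spec_of(c(110.1, 153.04), c(20, 100), precursor = 285.081)
  ft <- make_features(mz = 285.081, rt = 555,
                      intensities = list(c(s1 = 1)), ids = "M285T555",
                      ms2 = list(s))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(ft, path)
  back <- read_spectra(path)
  expect_equal(back$spectrum_id, "M285T555")
  expect_equal(back$spectrum[[1]]$peaks$mz, s$peaks$mz, tolerance = 1e-9)
  expect_equal(back$spectrum[[1]]$peaks$intensity, s$peaks$intensity,
               tolerance = 1e-7)
})
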