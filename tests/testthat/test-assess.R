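# Chimera detection, error reports, positional profiles

test_that("reads identical to references are never called chimeric", {
  set.seed(121)
  refs <- data.frame(id = sprintf("R%02d", 1:5),
                     seq = replicate(5, random_dna(300)))
  reads <- data.frame(id = paste0("q", 1:5), seq = refs$seq)
  chim <- detect_chimeras(reads, refs)
  expect_false(any(chim))
})

test_that("a constructed 4+4 split chimera is flagged; margin is strict", {
  set.seed(122)
  base <- strsplit(random_dna(300), "")[[1]]
  pa <- base; pb <- base
  # parents differ at 8 columns, 4 on each side of column 150
  for (at in c(30, 60, 90, 120)) pa[at] <- setdiff(c("A","C","G","T"),
                                                   base[at])[1]
  for (at in c(180, 210, 240, 270)) pb[at] <- setdiff(c("A","C","G","T"),
                                                      base[at])[1]
  refs <- data.frame(id = c("P", "Q"),
                     seq = c(paste(pa, collapse = ""),
                             paste(pb, collapse = "")))
  # chimera: P's prefix then Q's suffix -> 0 mismatches as a chimera,
  # 4 to either single parent
  chim_seq <- paste(c(pa[1:150], pb[151:300]), collapse = "")
  reads <- data.frame(id = "c1", seq = chim_seq)
  expect_true(detect_chimeras(reads, refs, margin = 3L)[["c1"]])
  expect_true(brute_force_chimera(chim_seq, refs$seq, margin = 3L))

  # improvement of exactly 2 stays below the margin
  pa2 <- base; pb2 <- base
  pa2[30] <- setdiff(c("A","C","G","T"), base[30])[1]
  pb2[270] <- setdiff(c("A","C","G","T"), base[270])[1]
  refs2 <- data.frame(id = c("P", "Q"),
                      seq = c(paste(pa2, collapse = ""),
                              paste(pb2, collapse = "")))
  chim2 <- paste(c(pa2[1:150], pb2[151:300]), collapse = "")
  expect_false(detect_chimeras(data.frame(id = "c2", seq = chim2),
                               refs2, margin = 3L)[["c2"]])
  expect_false(brute_force_chimera(chim2, refs2$seq, margin = 3L))
})

test_that("detect_chimeras equals the exhaustive brute force on random cases", {
  set.seed(123)
  for (rep in 1:15) {
    nref <- sample(3:6, 1)
    L <- sample(80:250, 1)
    anc <- strsplit(random_dna(L), "")[[1]]
    refs <- data.frame(id = sprintf("R%02d", seq_len(nref)),
                       seq = vapply(seq_len(nref), function(i) {
                         v <- anc
                         at <- sample(L, sample(4:12, 1))
                         v[at] <- sample(c("A","C","G","T"), length(at),
                                         replace = TRUE)
                         paste(v, collapse = "")
                       }, ""))
    reads <- data.frame(id = sprintf("q%d", 1:4), seq = vapply(1:4, function(i) {
      pr <- sample(nref, 2)
      bp <- sample(20:(L - 20), 1)
      v <- c(strsplit(refs$seq[pr[1]], "")[[1]][1:bp],
             strsplit(refs$seq[pr[2]], "")[[1]][(bp + 1):L])
      at <- sample(L, sample(0:2, 1))
      if (length(at)) v[at] <- sample(c("A","C","G","T"), length(at),
                                      replace = TRUE)
      paste(v, collapse = "")
    }, ""))
    got <- detect_chimeras(reads, refs)
    want <- vapply(reads$seq, brute_force_chimera, TRUE,
                   ref_seqs = refs$seq, USE.NAMES = FALSE)
    expect_equal(unname(got), want)
  }
})

test_that("fewer than two references disables chimera calling with a warning", {
  refs <- data.frame(id = "R1", seq = random_dna(100))
  reads <- data.frame(id = "q1", seq = refs$seq[1])
  expect_warning(chim <- detect_chimeras(reads, refs), "fewer than 2")
  expect_false(any(chim))
})

test_that("error rates follow the erroneous-over-total definition", {
  set.seed(124)
  refs <- data.frame(id = c("RA", "RB"),
                     seq = c(random_dna(100), random_dna(100)))
  v <- strsplit(refs$seq[1], "")[[1]]
  v[50] <- setdiff(c("A", "C", "G", "T"), v[50])[1]
  reads <- data.frame(id = c("clean1", "onesub"),
                      seq = c(refs$seq[1], paste(v, collapse = "")),
                      abundance = c(1L, 1L))
  rep <- compute_error_report(reads, refs)
  expect_equal(rep$error_rate, 1 / 200)
  expect_equal(rep$chimera_pct, 0)
  expect_equal(rep$per_read$n_sub, c(0L, 1L))

  # identical reads -> zero error rate
  rep0 <- compute_error_report(data.frame(id = "x", seq = refs$seq[2],
                                          abundance = 5L), refs)
  expect_equal(rep0$error_rate, 0)
})

test_that("error_rate is invariant to read order and abundance expansion", {
  sc <- get_scenario()
  reads <- sc$kept[1:30]
  records <- data.frame(id = vapply(reads, function(r) r$read_id, ""),
                        seq = vapply(reads, function(r) r$bases, ""),
                        abundance = 1L, stringsAsFactors = FALSE)
  r1 <- compute_error_report(records, sc$refs$records)
  r2 <- compute_error_report(records[rev(seq_len(nrow(records))), ],
                             sc$refs$records)
  expect_equal(r1$error_rate, r2$error_rate)
  # weighting one read by 3 equals listing it three times
  rec_w <- records; rec_w$abundance[5] <- 3L
  rec_dup <- rbind(records,
                   transform(records[c(5, 5), ],
                             id = c("dup1", "dup2")))
  expect_equal(compute_error_report(rec_w, sc$refs$records)$error_rate,
               compute_error_report(rec_dup, sc$refs$records)$error_rate)
})

test_that("positional profiles conserve event counts and see the decay trend", {
  sc <- get_scenario()
  reads <- sc$kept[1:150]
  records <- data.frame(id = vapply(reads, function(r) r$read_id, ""),
                        seq = vapply(reads, function(r) r$bases, ""),
                        abundance = 1L, stringsAsFactors = FALSE)
  rep <- compute_error_report(records, sc$refs$records)
  prof <- positional_profile(rep)
  expect_true(all(prof$total_rate >= 0 & prof$total_rate <= 1, na.rm = TRUE))
  expect_equal(sum(prof$total_rate * prof$coverage),
               sum(rep$per_read$n_sub + rep$per_read$n_ins +
                     rep$per_read$n_del))
  # signal degradation along the flowgram: error rate rises with position
  ok <- prof$coverage > 0
  expect_gt(stats::cor(prof$position[ok], prof$total_rate[ok],
                       method = "spearman"), 0.3)

  # error-free input profiles are all zero
  rep0 <- compute_error_report(data.frame(id = "x",
                                          seq = sc$refs$records$seq[1],
                                          abundance = 2L),
                               sc$refs$records)
  prof0 <- positional_profile(rep0)
  expect_true(all(prof0$total_rate == 0))
})
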