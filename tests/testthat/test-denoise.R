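# Template alignment, masking-aware preclustering, restoration

test_that("masked_aligned_read enforces its degap invariant", {
  r <- masked_aligned_read("m1", "AC-GT.", abundance = 3L,
                           mask_columns = c(2L, 4L))
  expect_equal(r$original, "ACGT")
  expect_error(masked_aligned_read("m2", "AC-GT", original = "ACT"),
               "degapped")
  expect_error(masked_aligned_read("m3", "ACGT", abundance = 0L), ">= 1")
})

test_that("identical reads merge into one cluster with summed abundance", {
  a <- masked_aligned_read("big", "ACGTACGT", abundance = 10L)
  b <- masked_aligned_read("small", "ACGTACGT", abundance = 1L)
  res <- precluster_masked(list(b, a))
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$clusters$seed_id, "big")
  expect_equal(res$clusters$abundance, 11L)
  expect_equal(unname(res$map["small"]), "big")
})

test_that("masking and the 2% budget control merging exactly", {
  L <- 100L
  set.seed(111)
  seed_seq <- random_dna(L)
  v <- strsplit(seed_seq, "")[[1]]
  mut1 <- v; mut1[40] <- setdiff(c("A", "C", "G", "T"), v[40])[1]
  mut3 <- v
  for (at in c(20, 50, 80)) mut3[at] <- setdiff(c("A", "C", "G", "T"),
                                                v[at])[1]
  seed_read <- masked_aligned_read("seed", seed_seq, abundance = 50L)
  # one differing column, masked in the singleton -> merged at zero diffs
  s1 <- masked_aligned_read("s1", paste(mut1, collapse = ""),
                            abundance = 1L, mask_columns = 40L)
  res <- precluster_masked(list(seed_read, s1))
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$merge_log$diffs_counted, 0L)
  expect_equal(res$merge_log$diffs_skipped, 1L)
  # unmasked single diff, budget floor(0.02*100) = 2 -> still merged
  s2 <- masked_aligned_read("s2", paste(mut1, collapse = ""), abundance = 1L)
  res2 <- precluster_masked(list(seed_read, s2))
  expect_equal(nrow(res2$clusters), 1L)
  expect_equal(res2$merge_log$diffs_counted, 1L)
  # three unmasked diffs -> not merged
  s3 <- masked_aligned_read("s3", paste(mut3, collapse = ""), abundance = 1L)
  res3 <- precluster_masked(list(seed_read, s3))
  expect_equal(nrow(res3$clusters), 2L)
})

test_that("preclustering equals the naive reference implementation", {
  set.seed(112)
  for (rep in 1:40) {
    n <- sample(4:40, 1)
    L <- sample(40:200, 1)
    mreads <- random_cluster_instance(n, L, seed = 1000 + rep)
    fast <- precluster_masked(mreads)
    naive <- naive_precluster(mreads)
    expect_identical(fast$map, naive$map)
    expect_identical(fast$clusters, naive$clusters)
  }
})

test_that("abundance is conserved and results are deterministic", {
  set.seed(113)
  for (rep in 1:10) {
    mreads <- random_cluster_instance(sample(5:30, 1), 120, seed = 2000 + rep)
    res <- precluster_masked(mreads)
    expect_equal(sum(res$clusters$abundance),
                 sum(vapply(mreads, function(r) r$abundance, 0L)))
    expect_identical(res, precluster_masked(mreads))
  }
})

test_that("restore_masks emits unmerged reads byte-identical to originals", {
  set.seed(114)
  mreads <- random_cluster_instance(20, 150, seed = 3000)
  res <- precluster_masked(mreads)
  originals <- stats::setNames(vapply(mreads, function(r) r$original, ""),
                               vapply(mreads, function(r) r$read_id, ""))
  out <- restore_masks(res, originals)
  expect_equal(out$id, res$clusters$seed_id)
  expect_identical(out$seq, unname(originals[out$id]))
  expect_equal(sum(out$abundance),
               sum(vapply(mreads, function(r) r$abundance, 0L)))
  expect_error(restore_masks(res, originals[-1]), "missing original")
})

test_that("with all masks empty the result equals plain preclustering", {
  set.seed(115)
  mreads <- random_cluster_instance(25, 150, seed = 4000)
  no_masks <- lapply(mreads, function(r) { r$mask_columns <- integer(); r })
  res_masked_empty <- precluster_masked(no_masks)
  plain <- naive_precluster(no_masks)
  expect_identical(res_masked_empty$map, plain$map)
  expect_identical(res_masked_empty$clusters, plain$clusters)
})

test_that("align_to_template projects reads NAST-style into template columns", {
  sc <- get_scenario()
  template <- sc$refs$records
  # a read identical to a template record maps onto it exactly
  rec <- data.frame(id = "t0", seq = template$seq[3], abundance = 1L)
  proj <- align_to_template(rec, template)
  expect_equal(gsub("[-.]", "", proj$reads[[1]]$aligned), template$seq[3])
  expect_equal(proj$maps[["t0"]], proj$template_column_map[1:400])

  # degap(aligned) == original for every simulated read
  reads <- sc$kept[1:60]
  records <- data.frame(id = vapply(reads, function(r) r$read_id, ""),
                        seq = vapply(reads, function(r) r$bases, ""),
                        abundance = 1L, stringsAsFactors = FALSE)
  proj2 <- align_to_template(records, template)
  for (mr in proj2$reads)
    expect_identical(gsub("[-.]", "", mr$aligned), mr$original)
  # all aligned strings share one width
  expect_length(unique(vapply(proj2$reads,
                              function(r) nchar(r$aligned), 0L)), 1)
  # masks transfer through the position -> column map
  masks <- list()
  masks[[records$id[1]]] <- c(5L, 17L)
  proj3 <- align_to_template(records[1, ], template, masks)
  mr <- proj3$reads[[1]]
  expect_equal(mr$mask_columns,
               sort(proj3$maps[[records$id[1]]][c(5L, 17L)]))
})

test_that("alignment-space distances agree with direct pairwise alignment", {
  # the merge decision only ever compares near-identical reads, so the
  # property is checked on pairs drawn from the same source reference
  sc <- get_scenario()
  reads <- sc$kept[1:80]
  records <- data.frame(id = vapply(reads, function(r) r$read_id, ""),
                        seq = vapply(reads, function(r) r$bases, ""),
                        abundance = 1L, stringsAsFactors = FALSE)
  truth_ids <- vapply(sc$sim$truth, function(tr) tr$read_id, "")
  truth_ref <- vapply(sc$sim$truth, function(tr) tr$reference_id,
                      "")[match(records$id, truth_ids)]
  proj <- align_to_template(records, sc$refs$records)
  M <- do.call(rbind, lapply(proj$reads,
                             function(r) strsplit(r$aligned, "")[[1]]))
  M[M == "."] <- "-"
  spans <- t(apply(M != "-", 1, function(z) range(which(z))))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(116)
  agree <- logical(0)
  for (k in 1:400) {
    ij <- sample(nrow(M), 2)
    if (truth_ref[ij[1]] != truth_ref[ij[2]]) next
    i <- ij[1]; j <- ij[2]
    a <- max(spans[i, 1], spans[j, 1]); b <- min(spans[i, 2], spans[j, 2])
    d_cols <- sum(M[i, a:b] != M[j, a:b])
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(records$seq[i]),
      Biostrings::DNAString(records$seq[j]), type = "global-local",
      substitutionMatrix = mat, gapOpening = 1, gapExtension = 1)
    ev <- label_errors(as.character(Biostrings::pattern(al)),
                       as.character(Biostrings::subject(al)))
    agree <- c(agree, d_cols == sum(ev$n))
  }
  expect_gt(length(agree), 20)
  expect_gte(mean(agree), 0.95)
})
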