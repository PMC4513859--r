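# End-to-end orchestration: prep -> fold -> evaluate -> context -> families
# -> expression, cross-linked by locus id, with a reproducibility manifest.

as_genome <- function(x) if (is.character(x)) read_genome_fasta(x) else x
as_features <- function(x) if (is.character(x)) read_gff3(x) else x
as_reads <- function(x, dialect = "collapsed_fasta") {
  if (is.character(x)) read_collapsed_reads(x, dialect) else x
}
as_candidates <- function(x) {
  if (is.character(x)) read_candidate_bed(x) else x
}

#' Run the full validation pipeline over a candidate set
#'
#' @param genome assembly tibble or FASTA path.
#' @param features annotation tibble or GFF3 path (introns derived).
#' @param reads collapsed-read tibble or FASTA path (`_x<count>` dialect).
#' @param candidates candidate locus tibble or BED path.
#' @param config a [criteria_config()].
#' @param filter a [read_filter_config()].
#' @param check_context run [extended_context_check()] on loci passing the
#'   four criteria (default TRUE).
#' @param out_dir optionally write all stage tables (see
#'   [write_result_tables()]).
#' @return object of class `mircert_run`: `summary` (one row per candidate:
#'   verdict, criteria measurements, context, cluster, family, expression),
#'   `accounting`, `stacks`, `folds`, `duplexes`, `mornas`, `certified`,
#'   `manifest`.
#' @export
run_all <- function(genome, features, reads, candidates,
                    config = criteria_config(),
                    filter = read_filter_config(),
                    check_context = TRUE, out_dir = NULL) {
  genome <- as_genome(genome)
  features <- as_features(features)
  reads_in <- as_reads(reads)
  candidates <- as_candidates(candidates)
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("no candidate loci supplied", call. = FALSE)
  }
  candidates <- arrange(candidates, .data$locus_id)

  prep <- filter_reads(reads_in, filter)
  freads <- prep$reads

  stacks <- list(); folds <- list(); rows <- list()
  for (i in seq_len(nrow(candidates))) {
    locus <- candidates[i, ]
    pre <- extract_locus_sequence(genome, locus$seq_id, locus$start,
                                  locus$end, locus$strand)
    f <- fold(pre)
    stack <- map_to_precursor(freads, pre, locus$locus_id)
    cls <- classify(locus, stack, f, config,
                    genome = if (check_context) genome else NULL,
                    reads = freads)
    stacks[[locus$locus_id]] <- stack
    folds[[locus$locus_id]] <- f
    rows[[locus$locus_id]] <- dplyr::bind_cols(
      locus[, c("seq_id", "start", "end", "strand")], cls)
  }
  summary <- bind_rows(rows) |>
    select("locus_id", dplyr::everything()) |>
    arrange(.data$locus_id)

  # library size: every retained read that maps somewhere, counted once
  mapped <- bind_rows(stacks)
  lib <- if (nrow(mapped) > 0) {
    sum(distinct(mapped, .data$sequence, .keep_all = TRUE)$count)
  } else {
    0
  }
  summary <- mutate(
    summary,
    mirna_rpm = ifelse(lib > 0 & !is.na(.data$mirna_count),
                       round(rpm_normalize(.data$mirna_count, lib), 2),
                       NA_real_),
    star_rpm = ifelse(lib > 0 & !is.na(.data$star_count),
                      round(rpm_normalize(.data$star_count, lib), 2),
                      NA_real_))

  ctx <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    genomic_context(candidates[i, ], features)
  })
  summary <- left_join(summary, ctx, by = "locus_id")

  certified <- filter(summary, .data$verdict == "VALID")
  if (nrow(certified) > 0) {
    clus <- find_clusters(certified[, c("locus_id", "seq_id", "start",
                                        "end")])
    summary <- left_join(summary,
                         clus[, c("locus_id", "cluster_id", "cluster_size")],
                         by = "locus_id")
    matures <- purrr::map_dfr(certified$locus_id, function(id) {
      s <- filter(summary, .data$locus_id == id)
      pre <- folds[[id]]$sequence
      tibble(locus_id = id,
             mature_seq = substr(pre, s$mirna_start, s$mirna_end),
             star_seq = ifelse(is.na(s$star_start), NA_character_,
                               substr(pre, s$star_start, s$star_end)))
    })
    fam <- assign_families(matures, mode = "seed")
    summary <- left_join(summary,
                         fam[, c("locus_id", "family_id", "family_size")],
                         by = "locus_id") |>
      left_join(matures, by = "locus_id")
  } else {
    summary <- mutate(summary, cluster_id = NA_character_,
                      cluster_size = NA_integer_, family_id = NA_character_,
                      family_size = NA_integer_,
                      mature_seq = NA_character_, star_seq = NA_character_)
  }

  mornas <- purrr::map_dfr(certified$locus_id, function(id) {
    s <- filter(summary, .data$locus_id == id)
    duplex <- tibble(mirna_start = s$mirna_start, mirna_end = s$mirna_end,
                     star_start = s$star_start, star_end = s$star_end)
    mutate(detect_mornas(stacks[[id]], duplex, folds[[id]], config),
           locus_id = id)
  })

  manifest <- tibble(
    key = c("tool_version", "n_candidates", "n_reads_in", "n_reads_retained",
            "library_size", "n_valid", "n_weak", "n_reject",
            "digest_genome", "digest_features", "digest_reads",
            "digest_candidates", "digest_summary"),
    value = as.character(c(
      as.character(utils::packageVersion("mircert")),
      nrow(candidates), sum(reads_in$count), sum(freads$count), lib,
      sum(summary$verdict == "VALID"), sum(summary$verdict == "WEAK"),
      sum(summary$verdict == "REJECT"),
      digest::digest(genome), digest::digest(features),
      digest::digest(reads_in), digest::digest(candidates),
      digest::digest(summary))))

  run <- structure(list(summary = summary, accounting = prep$accounting,
                        stacks = stacks, folds = folds, mornas = mornas,
                        certified = filter(summary,
                                           .data$verdict == "VALID"),
                        manifest = manifest, config = config),
                   class = "mircert_run")
  if (!is.null(out_dir)) write_result_tables(run, out_dir)
  run
}

#' Run the pipeline directly on a synthetic dataset
#' @param dataset a `mircert_dataset` from [generate_dataset()].
#' @param ... passed to [run_all()].
#' @return a `mircert_run`.
#' @export
run_on_dataset <- function(dataset, ...) {
  run_all(dataset$genome, dataset$features, dataset$reads,
          dataset$candidates, ...)
}

#' @export
print.mircert_run <- function(x, ...) {
  v <- table(factor(x$summary$verdict, c("VALID", "WEAK", "REJECT")))
  cat("<mircert_run> ", nrow(x$summary), " candidate loci: ",
      v["VALID"], " VALID, ", v["WEAK"], " WEAK, ", v["REJECT"],
      " REJECT\n", sep = "")
  invisible(x)
}

#' Tidy the per-locus summary of a pipeline run
#' @param x a `mircert_run`.
#' @param ... unused.
#' @return the summary tibble.
#' @export
tidy.mircert_run <- function(x, ...) x$summary

#' One-row summary of a pipeline run
#' @param x a `mircert_run`.
#' @param ... unused.
#' @return tibble with verdict counts and library accounting.
#' @export
glance.mircert_run <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$summary),
    n_valid = sum(x$summary$verdict == "VALID"),
    n_weak = sum(x$summary$verdict == "WEAK"),
    n_reject = sum(x$summary$verdict == "REJECT"),
    reads_retained =
      x$accounting$reads[x$accounting$cause == "retained"],
    library_size =
      as.numeric(x$manifest$value[x$manifest$key == "library_size"])
  )
}

#' Write all stage tables of a run
#'
#' Tab-separated tables with fixed column order and lexicographic locus-id
#' row order, plus GFF3 for certified loci; identical runs produce
#' byte-identical files.
#'
#' @param run a `mircert_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_result_tables <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  }
  w(run$summary, "summary.tsv")
  w(run$accounting, "read_accounting.tsv")
  w(run$mornas, "mornas.tsv")
  w(run$manifest, "manifest.tsv")
  cert <- run$certified
  gff <- if (nrow(cert) > 0) {
    cert[, c("locus_id", "seq_id", "start", "end", "strand",
             "star_start", "star_end")] |>
      mutate(mature_start = cert$mirna_start, mature_end = cert$mirna_end)
  } else {
    tibble(locus_id = character(), seq_id = character(), start = integer(),
           end = integer(), strand = character(),
           mature_start = integer(), mature_end = integer(),
           star_start = integer(), star_end = integer())
  }
  write_mirna_gff3(gff, file.path(out_dir, "certified.gff3"))
  invisible(out_dir)
}

#' Fixed-width text rendering of a read stack on its hairpin
#'
#' Produces the classic per-locus diagram: precursor sequence (RNA
#' letters), dot-bracket structure, a marker line for the miRNA (`m`) and
#' miRNA* (`*`) intervals, then one line per distinct read with offset
#' padding and an `x<count>` suffix.
#'
#' @param stack read-stack tibble.
#' @param fold the precursor `hairpin_fold`.
#' @param duplex optional duplex tibble from [call_products()].
#' @return character vector of lines.
#' @export
render_locus <- function(stack, fold, duplex = NULL) {
  n <- nchar(fold$sequence)
  lines <- c(as_rna(fold$sequence), fold$structure)
  if (!is.null(duplex) && !is.na(duplex$mirna_start)) {
    mark <- rep(" ", n)
    mark[duplex$mirna_start:duplex$mirna_end] <- "m"
    if (!is.na(duplex$star_start)) {
      mark[duplex$star_start:duplex$star_end] <- "*"
    }
    lines <- c(lines, paste(mark, collapse = ""))
  }
  if (nrow(stack) > 0) {
    stack <- arrange(stack, .data$start, dplyr::desc(.data$count))
    lines <- c(lines, vapply(seq_len(nrow(stack)), function(i) {
      paste0(strrep(" ", stack$start[i] - 1L),
             as_rna(stack$sequence[i]),
             strrep(" ", n - stack$end[i]),
             sprintf(" x%d", stack$count[i]))
    }, character(1)))
  }
  lines
}
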