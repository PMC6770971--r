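#' Methylation count tables
#'
#' `bfmeth` represents per-CpG methylation counts as a long tibble with one
#' row per sample x site: columns `chrom`, `pos` (1-based bp), `sample`,
#' `group` (ordinal integer 1..K), `meth` (methylated read count) and `cov`
#' (total coverage). Sites absent from a sample are kept with `cov = 0`, so
#' the table is a complete sample-by-site grid. `validate_meth_data()`
#' checks the invariants and returns the table sorted by position.
#'
#' @param data A data frame with the columns above.
#' @return `data` as a tibble, sorted by `chrom`, `pos`, `sample`.
#' @examples
#' validate_meth_data(tibble::tibble(
#'   chrom = "chr1", pos = c(100L, 100L), sample = c("a", "b"),
#'   group = c(1L, 2L), meth = c(3L, 5L), cov = c(10L, 10L)
#' ))
#' @export
validate_meth_data <- function(data) {
  req <- c("chrom", "pos", "sample", "group", "meth", "cov")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("methylation data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (any(data$meth < 0) || any(data$cov < 0) || any(data$meth > data$cov)) {
    stop("methylation counts must satisfy 0 <= meth <= cov", call. = FALSE)
  }
  groups <- sort(unique(data$group))
  K <- max(groups)
  if (!identical(as.integer(groups), seq_len(K))) {
    stop("group labels must be consecutive integers 1..K with every ",
         "group represented; saw {", paste(groups, collapse = ", "), "}",
         call. = FALSE)
  }
  grid <- dplyr::count(data, .data$chrom, .data$pos, .data$sample)
  if (any(grid$n > 1)) {
    stop("duplicate (chrom, pos, sample) rows in methylation data",
         call. = FALSE)
  }
  dplyr::arrange(data, .data$chrom, .data$pos, .data$sample)
}

#' Read bismark-style coverage files into a methylation table
#'
#' Reads one tab-separated coverage file per sample (columns: chrom, start,
#' end, methylation percentage, methylated count, unmethylated count) and
#' joins them with a sample sheet assigning each sample its ordinal group.
#' Both circulating coordinate dialects are accepted: `end == start`
#' (1-based inclusive, the bismark `.cov` convention) and
#' `end == start + 1`; in both cases `start` is taken as the site position.
#' Sites present in any sample are kept for all samples, with zero coverage
#' where a sample has no reads.
#'
#' @param paths Character vector of coverage file paths, one per sample.
#' @param sample_sheet Data frame with columns `sample` and `group`
#'   (ordinal integers 1..K), or the path of a TSV with those columns.
#'   Samples are matched to `paths` by file base name with extensions
#'   stripped, unless `sample_sheet` has a `path` column.
#' @return A methylation tibble (see [validate_meth_data()]).
#' @export
read_bismark_cov <- function(paths, sample_sheet) {
  if (is.character(sample_sheet) && length(sample_sheet) == 1) {
    sample_sheet <- read_sample_sheet(sample_sheet)
  }
  sample_sheet <- tibble::as_tibble(sample_sheet)
  if (!all(c("sample", "group") %in% names(sample_sheet))) {
    stop("sample sheet needs columns 'sample' and 'group'", call. = FALSE)
  }

  per_sample <- purrr::map2(paths, seq_along(paths), function(path, idx) {
    raw <- tryCatch(
      readr::read_tsv(path,
        col_names = c("chrom", "start", "end", "meth_pct", "meth", "unmeth"),
        col_types = "ciidii", progress = FALSE, comment = "#"
      ),
      error = function(e) {
        stop("failed to parse coverage file '", path, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
    bad <- which(is.na(raw$start) | is.na(raw$meth) | is.na(raw$unmeth) |
                   raw$meth < 0 | raw$unmeth < 0)
    if (length(bad) > 0) {
      stop("malformed line ", bad[1], " in coverage file '", path, "'",
           call. = FALSE)
    }
    ok_dialect <- raw$end == raw$start | raw$end == raw$start + 1
    if (!all(ok_dialect)) {
      stop("malformed line ", which(!ok_dialect)[1], " in coverage file '",
           path, "': end must equal start or start + 1", call. = FALSE)
    }
    sample_id <- sub("\\.(cov|txt|tsv)(\\.gz)?$", "", basename(path))
    tibble::tibble(
      chrom = raw$chrom, pos = raw$start, sample = sample_id,
      meth = raw$meth, cov = raw$meth + raw$unmeth
    )
  })
  counts <- dplyr::bind_rows(per_sample)

  unmatched <- setdiff(unique(counts$sample), sample_sheet$sample)
  if (length(unmatched) > 0) {
    stop("sample(s) missing from sample sheet: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  sheet <- dplyr::filter(sample_sheet, .data$sample %in% unique(counts$sample))

  # complete sample x site grid with zero-coverage fill
  sites <- dplyr::distinct(counts, .data$chrom, .data$pos)
  grid <- tidyr::crossing(sites, sample = sheet$sample)
  full <- dplyr::left_join(grid, counts, by = c("chrom", "pos", "sample"))
  full <- dplyr::mutate(full,
    meth = dplyr::coalesce(.data$meth, 0L),
    cov = dplyr::coalesce(.data$cov, 0L)
  )
  full <- dplyr::left_join(full,
    dplyr::select(sheet, "sample", "group"), by = "sample")
  validate_meth_data(
    dplyr::select(full, "chrom", "pos", "sample", "group", "meth", "cov"))
}

#' Read a sample sheet
#'
#' @param path TSV with header columns `sample` and `group`.
#' @return A tibble with `sample` (character) and `group` (integer).
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("sample", "group") %in% names(sheet))) {
    stop("sample sheet '", path, "' needs columns 'sample' and 'group'",
         call. = FALSE)
  }
  dplyr::mutate(sheet, sample = as.character(.data$sample),
                group = as.integer(.data$group))
}

#' Write a methylation table as per-sample bismark coverage files
#'
#' Inverse of [read_bismark_cov()]: writes one `<sample>.cov` file per
#' sample (1-based, `end == start`, zero-coverage sites omitted) plus a
#' `sample_sheet.tsv` into `dir`.
#'
#' @param data Methylation tibble.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths of the coverage files written.
#' @export
write_bismark_cov <- function(data, dir) {
  data <- validate_meth_data(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sheet <- dplyr::distinct(data, .data$sample, .data$group)
  readr::write_tsv(sheet, file.path(dir, "sample_sheet.tsv"))
  paths <- purrr::map_chr(split(data, data$sample), function(d) {
    d <- dplyr::filter(d, .data$cov > 0)
    out <- tibble::tibble(
      chrom = d$chrom, start = d$pos, end = d$pos,
      meth_pct = ifelse(d$cov > 0, 100 * d$meth / d$cov, 0),
      meth = d$meth, unmeth = d$cov - d$meth
    )
    path <- file.path(dir, paste0(d$sample[1], ".cov"))
    readr::write_tsv(out, path, col_names = FALSE)
    path
  })
  invisible(unname(paths))
}

#' Write significant windows or DMRs as BED6
#'
#' Emits one BED line (0-based, half-open) per window with Bayes factor
#' above `threshold`. The score column carries `log10(BF)` clipped to
#' `[0, 1000]` (censored/infinite Bayes factors map to 1000); the name
#' column carries the Jeffreys evidence category.
#'
#' @param windows Tibble of window results (from [scan_bfm()] or
#'   [call_dmrs()]), sorted by genomic position.
#' @param path Output file path.
#' @param threshold Minimum Bayes factor (exclusive) for a window to be
#'   written. Default 3 (Jeffreys "positive").
#' @return Invisibly, the number of lines written.
#' @export
write_dmr_bed <- function(windows, path, threshold = 3) {
  if (nrow(windows) > 0) {
    o <- order(windows$chrom, windows$start_bp)
    if (!identical(o, seq_len(nrow(windows)))) {
      stop("windows must be sorted by chromosome and start position",
           call. = FALSE)
    }
  }
  keep <- windows[windows$bf > threshold, , drop = FALSE]
  lines <- "# bfmeth DMR windows (BED6); score = log10(BF) clipped to [0,1000]"
  if (nrow(keep) > 0) {
    cens <- if ("bf_censored" %in% names(keep)) keep$bf_censored
            else rep(FALSE, nrow(keep))
    score <- ifelse(is.infinite(keep$bf) | cens, 1000, log10(keep$bf))
    score <- pmin(pmax(score, 0), 1000)
    name <- if ("evidence" %in% names(keep)) as.character(keep$evidence)
            else "."
    lines <- c(lines, paste(keep$chrom, keep$start_bp - 1, keep$end_bp,
                            name, sprintf("%.8g", score), ".",
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(nrow(keep))
}
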