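#' Read an OTU count table
#'
#' Reads gradient-fraction amplicon count tables in either the mothur
#' "shared" dialect (one row per sample; header columns `label`, `Group`,
#' `numOtus`, then one column per OTU) or a plain TSV matrix (one row per
#' taxon, first column taxon ids, one column per sample).
#'
#' @param path Path to the file.
#' @param dialect `"mothur_shared"` or `"tsv"`.
#' @param meta Optional fraction metadata: a data frame as accepted by
#'   [sip_table()], or a path to a YAML metadata file (see
#'   [read_fraction_meta()]). When omitted, placeholder metadata with
#'   `fraction_role = "other"` is attached; a screening run then requires
#'   real metadata.
#'
#' @return A [sip_table()].
#' @export
read_shared_table <- function(path, dialect = c("mothur_shared", "tsv"),
                              meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_io(sprintf("count table file not found: %s", path))
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )

  if (dialect == "mothur_shared") {
    required <- c("label", "Group", "numOtus")
    missing <- setdiff(required, names(raw))
    if (length(missing) > 0L) {
      stop_format(sprintf(
        "malformed mothur shared header: missing column '%s'", missing[1L]
      ))
    }
    otu_cols <- setdiff(names(raw), required)
    if (length(otu_cols) == 0L) {
      stop_format("mothur shared file contains no OTU columns")
    }
    if (anyDuplicated(raw$Group)) {
      stop_validation("duplicate Group names in mothur shared file")
    }
    num_otus <- suppressWarnings(as.integer(raw$numOtus))
    bad <- which(is.na(num_otus) | num_otus != length(otu_cols))
    if (length(bad) > 0L) {
      stop_validation(sprintf(
        "numOtus (%s) does not match the %d OTU columns present (Group '%s')",
        raw$numOtus[bad[1L]], length(otu_cols), raw$Group[bad[1L]]
      ))
    }
    counts <- tibble::tibble(otu_id = otu_cols)
    for (i in seq_len(nrow(raw))) {
      x <- suppressWarnings(as.numeric(unlist(raw[i, otu_cols])))
      bad <- which(!is.finite(x) | x < 0 | x != round(x))
      if (length(bad) > 0L) {
        stop_validation(sprintf(
          "counts must be non-negative integers; offending value '%s' for Group '%s', OTU '%s'",
          as.character(raw[i, otu_cols[bad[1L]]]), raw$Group[i], otu_cols[bad[1L]]
        ))
      }
      counts[[raw$Group[i]]] <- as.integer(round(x))
    }
  } else {
    if (ncol(raw) < 2L) {
      stop_format("tsv count matrix needs a taxon id column plus sample columns")
    }
    counts <- raw
    names(counts)[1L] <- "otu_id"
  }

  if (is.null(meta)) {
    sample_ids <- setdiff(names(counts), "otu_id")
    meta <- tibble::tibble(
      sample_id = sample_ids,
      isotope = NA_character_,
      fraction_role = "other",
      treatment = NA_character_,
      density = NA_real_
    )
  } else if (is.character(meta) && length(meta) == 1L) {
    meta <- read_fraction_meta(meta)
  }
  sip_table(counts, meta)
}

#' Write an OTU count table
#'
#' Inverse of [read_shared_table()]; round-trips counts, identifiers and
#' ordering exactly in both dialects.
#'
#' @param x A [sip_table()].
#' @param path Output path.
#' @param dialect `"mothur_shared"` or `"tsv"`.
#' @param label Distance label written to the mothur `label` column.
#' @return `path`, invisibly.
#' @export
write_shared_table <- function(x, path, dialect = c("mothur_shared", "tsv"),
                               label = "0.03") {
  stopifnot(inherits(x, "sip_table"))
  dialect <- match.arg(dialect)
  out <- if (dialect == "mothur_shared") {
    wide <- tibble::tibble(
      label = label,
      Group = setdiff(names(x$counts), "otu_id"),
      numOtus = nrow(x$counts)
    )
    m <- t(as.matrix(x$counts[, -1L, drop = FALSE]))
    colnames(m) <- x$counts$otu_id
    dplyr::bind_cols(wide, tibble::as_tibble(m))
  } else {
    x$counts
  }
  with_io_errors(readr::write_tsv(out, path, progress = FALSE), path)
  invisible(path)
}

with_io_errors <- function(expr, path) {
  tryCatch(expr, error = function(e) {
    stop_io(sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  })
}

#' Read fraction metadata from YAML
#'
#' The file maps sample ids to their fraction metadata:
#' ```yaml
#' H13_starch: {isotope: C13, fraction_role: heavy, treatment: starch, density: 1.725}
#' L13_starch: {isotope: C13, fraction_role: light, treatment: starch, density: 1.700}
#' ```
#'
#' @param path Path to a YAML file.
#' @return A tibble with columns `sample_id`, `isotope`, `fraction_role`,
#'   `treatment`, `density`.
#' @export
read_fraction_meta <- function(path) {
  if (!file.exists(path)) {
    stop_io(sprintf("fraction metadata file not found: %s", path))
  }
  y <- yaml::read_yaml(path)
  if (length(y) == 0L) {
    stop_format(sprintf("fraction metadata file '%s' is empty", path))
  }
  rows <- purrr::imap(y, function(rec, sid) {
    tibble::tibble(
      sample_id = sid,
      isotope = rec$isotope %||% NA_character_,
      fraction_role = rec$fraction_role %||% "other",
      treatment = rec$treatment %||% NA_character_,
      density = rec$density %||% NA_real_
    )
  })
  validate_fraction_meta(purrr::list_rbind(rows))
}

#' Write fraction metadata to YAML
#'
#' @param meta Fraction metadata tibble (see [read_fraction_meta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fraction_meta <- function(meta, path) {
  meta <- validate_fraction_meta(meta)
  y <- lapply(seq_len(nrow(meta)), function(i) {
    rec <- list(
      isotope = meta$isotope[i],
      fraction_role = meta$fraction_role[i],
      treatment = meta$treatment[i]
    )
    if (!is.na(meta$density[i])) rec$density <- meta$density[i]
    rec
  })
  names(y) <- meta$sample_id
  with_io_errors(yaml::write_yaml(y, path), path)
  invisible(path)
}

tax_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

#' Read a taxonomy assignment table
#'
#' Accepts mothur `cons.taxonomy`-style files (columns OTU, Size, Taxonomy)
#' or plain two-column TSV (otu id, semicolon-separated lineage). Bootstrap
#' values in parentheses are stripped and lineages are padded to genus with
#' `"unclassified"`.
#'
#' @param path Path to the file.
#' @return A tibble with columns `otu_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) {
    stop_io(sprintf("taxonomy file not found: %s", path))
  }
  empty <- tibble::as_tibble(
    c(list(otu_id = character(0)),
      setNames(rep(list(character(0)), length(tax_ranks)), tax_ranks))
  )
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty)
  }
  has_header <- grepl("^OTU\\b", lines[1L], ignore.case = TRUE)
  if (has_header) lines <- lines[-1L]
  if (length(lines) == 0L) {
    return(empty)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  otu_id <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(otu_id)) {
    stop_validation(sprintf(
      "duplicate otu_id in taxonomy file: %s",
      paste(unique(otu_id[duplicated(otu_id)]), collapse = ", ")
    ))
  }
  lineage <- vapply(parts, function(p) p[[length(p)]], character(1))
  ranks <- purrr::map(lineage, parse_lineage)
  dplyr::bind_cols(
    tibble::tibble(otu_id = otu_id),
    purrr::list_rbind(purrr::map(ranks, function(r) {
      tibble::as_tibble(as.list(setNames(r, tax_ranks)))
    }))
  )
}

parse_lineage <- function(lineage) {
  lineage <- gsub("\\([^)]*\\)", "", lineage)
  levels <- strsplit(lineage, ";", fixed = TRUE)[[1L]]
  levels <- trimws(levels)
  levels <- levels[nzchar(levels)]
  n <- length(tax_ranks)
  out <- rep("unclassified", n)
  take <- min(length(levels), n)
  if (take > 0L) out[seq_len(take)] <- levels[seq_len(take)]
  out
}

#' Look up lineages for a set of taxa
#'
#' Absent taxa yield a fully `"unclassified"` lineage rather than an error.
#'
#' @param taxonomy A taxonomy tibble from [read_taxonomy()], or `NULL`.
#' @param otu_ids Character vector of taxon identifiers.
#' @return A tibble with one row per element of `otu_ids` and the rank
#'   columns of [read_taxonomy()].
#' @export
lookup_lineage <- function(taxonomy, otu_ids) {
  out <- tibble::tibble(otu_id = as.character(otu_ids))
  if (is.null(taxonomy) || nrow(taxonomy) == 0L) {
    for (r in tax_ranks) out[[r]] <- "unclassified"
    return(out)
  }
  out <- dplyr::left_join(out, taxonomy, by = "otu_id")
  for (r in tax_ranks) {
    out[[r]] <- dplyr::coalesce(out[[r]], "unclassified")
  }
  out
}

#' Write the labelled-taxon screening report
#'
#' One TSV row per tested taxon, carrying both stratum odds ratios, the
#' Breslow-Day statistic and p-value, Holm rank/threshold/decision, the
#' direction of the call, and significance stars. Stars reflect the Holm
#' step-down decision rerun at each conventional level: `*` significant at
#' alpha = 0.05, `**` at 0.01, `***` at 0.001. Rows are ordered by Holm rank,
#' ties (equal p) by `otu_id`.
#'
#' @param calls A screening result from [run_labelling_screen()] (possibly
#'   with zero rows).
#' @param taxonomy Optional taxonomy tibble from [read_taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_report <- function(calls, taxonomy = NULL, path) {
  calls <- tibble::as_tibble(calls)
  cols <- c("otu_id", "lineage", "direction", "or_c12", "or_c13", "or_mh",
            "statistic", "p_value", "holm_rank", "holm_threshold",
            "significant", "significance")
  if (nrow(calls) == 0L) {
    out <- tibble::as_tibble(setNames(rep(list(character(0)), length(cols)), cols))
    with_io_errors(readr::write_tsv(out, path, progress = FALSE), path)
    return(invisible(path))
  }
  lin <- lookup_lineage(taxonomy, calls$otu_id)
  lineage <- apply(as.matrix(lin[, tax_ranks]), 1L, paste, collapse = ";")
  out <- calls
  out$lineage <- lineage
  out$significance <- significance_stars(calls$p_value)
  out <- out[order(out$holm_rank, out$otu_id), cols]
  with_io_errors(readr::write_tsv(out, path, progress = FALSE), path)
  invisible(path)
}

# Holm-adjusted decisions at the conventional star levels.
significance_stars <- function(p) {
  stars <- rep("", length(p))
  for (a in c(0.05, 0.01, 0.001)) {
    sig <- holm_bonferroni(p, alpha = a)$significant
    stars[sig] <- paste0(stars[sig], "*")
  }
  stars
}
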