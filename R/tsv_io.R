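# Tab-separated table I/O. All tables carry a '#'-prefixed header row;
# object-level attributes (cutoff, ensemble size, ...) are stored as
# '#!key=value' comment lines so that write -> read round-trips the object.

format_tsv_value <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    # fixed formatting keeps reruns byte-identical and round-trippable
    out <- formatC(x, format = "g", digits = 15)
    out[is.na(x)] <- "NA"
    out
  } else as.character(x)
}

write_tsv_impl <- function(df, path, attrs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(attrs)) {
    for (k in names(attrs)) {
      writeLines(sprintf("#!%s=%s", k, format_tsv_value(attrs[[k]])), con)
    }
  }
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    cols <- lapply(df, format_tsv_value)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

read_tsv_impl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  attr_lines <- grep("^#!", lines)
  attrs <- list()
  for (i in attr_lines) {
    kv <- sub("^#!", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    attrs[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
  }
  body <- lines[setdiff(seq_along(lines), attr_lines)]
  # leading '#' lines are comments; the last of them is the column header
  lead <- which(startsWith(body, "#"))
  lead <- lead[lead == seq_along(lead)]
  header_i <- if (length(lead)) lead[length(lead)] else NA_integer_
  if (is.na(header_i)) stop("no '#'-prefixed header row in ", path)
  cols <- strsplit(sub("^#", "", body[header_i]), "\t", fixed = TRUE)[[1L]]
  data_lines <- body[-seq_len(header_i)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (!length(data_lines)) {
    df <- as.data.frame(stats::setNames(replicate(length(cols), character(0), simplify = FALSE), cols),
                        stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(data_lines, "\t", fixed = TRUE)
    mat <- do.call(rbind, lapply(parts, function(p) {
      length(p) <- length(cols)
      p
    }))
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- cols
    for (j in seq_along(df)) {
      v <- df[[j]]
      suppress <- suppressWarnings(as.numeric(v))
      if (all(!is.na(suppress) | v %in% c("NA", ""))) {
        suppress[v %in% c("NA", "")] <- NA_real_
        df[[j]] <- suppress
      }
    }
  }
  attr(df, "file_attrs") <- attrs
  df
}

#' Write analysis tables as TSV
#'
#' Dispatches on the object class (contact maps, interaction-frequency
#' tables, selection results). Row order is deterministic: sorted by receptor
#' residue number, then peptide residue number, then conformation id. All
#' files round-trip through [read_tables()].
#'
#' @param obj an `ecl2_contact_map`, `ecl2_freq_table` or `ecl2_selection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tables <- function(obj, path) UseMethod("write_tables")

sort_contact_rows <- function(df) {
  rk <- parse_res_key(df$receptor)
  pk <- parse_res_key(df$peptide)
  cid <- if ("conformation_id" %in% names(df)) df$conformation_id else rep(0L, nrow(df))
  df[order(rk$resno, pk$resno, cid), , drop = FALSE]
}

#' @export
write_tables.ecl2_contact_map <- function(obj, path) {
  df <- sort_contact_rows(as.data.frame(obj))
  write_tsv_impl(df, path, attrs = list(
    class = "ecl2_contact_map",
    cutoff = attr(obj, "cutoff"),
    ensemble_size = attr(obj, "ensemble_size")
  ))
}

#' @export
write_tables.ecl2_freq_table <- function(obj, path) {
  df <- sort_contact_rows(as.data.frame(obj))
  write_tsv_impl(df, path, attrs = list(
    class = "ecl2_freq_table",
    ensemble_size = attr(obj, "ensemble_size"),
    min_count = attr(obj, "min_count")
  ))
}

#' @export
write_tables.ecl2_selection <- function(obj, path) {
  df <- as.data.frame(obj)
  df <- df[order(df$conformation_id), , drop = FALSE]
  write_tsv_impl(df, path, attrs = list(
    class = "ecl2_selection",
    ranking = paste(attr(obj, "ranking"), collapse = ",")
  ))
}

#' @rdname write_tables
#' @return `read_tables()`: the object written, with class and attributes
#'   restored.
#' @export
read_tables <- function(path) {
  df <- read_tsv_impl(path)
  attrs <- attr(df, "file_attrs")
  attr(df, "file_attrs") <- NULL
  cls <- attrs$class
  if (is.null(cls)) stop("table at ", path, " has no class annotation")
  if (cls == "ecl2_contact_map") {
    if ("conformation_id" %in% names(df)) df$conformation_id <- as.integer(df$conformation_id)
    if ("count" %in% names(df)) df$count <- as.integer(df$count)
    out <- structure(df, class = c("ecl2_contact_map", "data.frame"),
                     cutoff = as.numeric(attrs$cutoff),
                     ensemble_size = as.integer(attrs$ensemble_size))
  } else if (cls == "ecl2_freq_table") {
    df$count <- as.integer(df$count)
    out <- structure(df, class = c("ecl2_freq_table", "data.frame"),
                     ensemble_size = as.integer(attrs$ensemble_size),
                     min_count = as.integer(attrs$min_count))
  } else if (cls == "ecl2_selection") {
    df$conformation_id <- as.integer(df$conformation_id)
    for (cc in intersect(c("mandatory_ok", "key_ok", "score_ok", "orientation_ok", "selected"),
                         names(df))) {
      df[[cc]] <- as.logical(df[[cc]])
    }
    ranking <- if (nzchar(attrs$ranking)) as.integer(strsplit(attrs$ranking, ",")[[1L]]) else integer(0)
    out <- structure(df, class = c("ecl2_selection", "data.frame"), ranking = ranking)
  } else stop("unknown table class: ", cls)
  rownames(out) <- NULL
  out
}
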