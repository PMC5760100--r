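#' Canonical hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; stamped into every output file
#' so reruns are auditable.
#' @param config any R list.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

# Write a CSV with a provenance comment line (readable back with
# read.csv(comment.char = "#")).
write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# punctatrack config_hash=%s seed=%s", hash,
                     paste(seed, collapse = ",")), con)
  drop <- vapply(df, is.list, logical(1))
  utils::write.csv(df[, !drop, drop = FALSE], con, row.names = FALSE)
  invisible(path)
}

#' Write per-photoreceptor results in the deposited-table layout
#'
#' Two plain-text tables mirroring the study's deposited spreadsheet: a
#' "Kinetics" table (Displacement, Trajectory, Size, Maximum Speed; one row
#' per photoreceptor, condition in a column) and a "Contacts" table
#' (proportion and absolute number of contacting puncta per photoreceptor).
#'
#' @param summaries per-photoreceptor summary table ([summarize_pr()] rows).
#' @param dir output directory (created if needed).
#' @return paths of the two CSV files, invisibly.
#' @export
write_s1_tables <- function(summaries, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kin <- data.frame(
    Condition = summaries$condition,
    Animal = summaries$animal_id,
    PR = summaries$cell_id,
    Displacement = summaries$displacement_nm,
    Trajectory = summaries$trajectory_um,
    Size = summaries$area_um2,
    `Maximum Speed` = summaries$max_speed_nm_s,
    check.names = FALSE
  )
  con <- data.frame(
    Condition = summaries$condition,
    Animal = summaries$animal_id,
    PR = summaries$cell_id,
    `Proportion contacting` = summaries$contact_proportion,
    `Number contacting` = summaries$n_contacting,
    check.names = FALSE
  )
  pk <- file.path(dir, "kinetics.csv")
  pc <- file.path(dir, "contacts.csv")
  utils::write.csv(kin, pk, row.names = FALSE)
  utils::write.csv(con, pc, row.names = FALSE)
  invisible(c(kinetics = pk, contacts = pc))
}

# header synonym map: canonical metric name -> accepted (lower-cased,
# squeezed) column headings
s1_synonyms <- list(
  displacement = c("displacement", "displacement nm", "displacement (nm)"),
  trajectory = c("trajectory", "trajectory um", "trajectory (um)",
                 "total trajectory"),
  size = c("size", "area", "size um2", "area um2", "cross-sectional area"),
  max_speed = c("maximum speed", "max speed", "max. speed",
                "maximum speed nm/s"),
  contact_proportion = c("proportion contacting", "proportion",
                         "contacting proportion", "proportion of contacting"),
  n_contacting = c("number contacting", "number", "absolute number",
                   "n contacting")
)

normalize_heading <- function(x) {
  x <- tolower(trimws(x))
  gsub("[._]+", " ", x)
}

match_headings <- function(headings, wanted) {
  norm <- normalize_heading(headings)
  out <- integer(0)
  for (canon in wanted) {
    hit <- which(norm %in% s1_synonyms[[canon]])
    if (length(hit) == 0L) {
      stop(sprintf(
        "expected a column for '%s' (accepted headings: %s); got: %s",
        canon, paste(s1_synonyms[[canon]], collapse = ", "),
        paste(headings, collapse = ", ")))
    }
    out[canon] <- hit[1]
  }
  out
}

read_s1_sheet <- function(path, sheet) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, check.names = FALSE, comment.char = "#")
  }
}

#' Read a deposited-style per-photoreceptor result table
#'
#' Reads the "Kinetics" and "Contacts" tables — either a directory holding
#' `kinetics.csv` and `contacts.csv` (as written by [write_s1_tables()]) or
#' a spreadsheet (`.xlsx`) with sheets named "Kinetics" and "Contacts" —
#' into a long-format study table. Column headings are matched
#' case-insensitively against documented synonyms (e.g. "Size" or "Area");
#' a `Condition` column is required, `Animal`/`PR` identifier columns are
#' optional (rows are numbered per condition when absent).
#'
#' @param path directory or spreadsheet file.
#' @return long-format data.frame `animal_id`, `cell_id`, `condition`,
#'   `metric`, `value` with metrics `displacement` (nm), `trajectory` (um),
#'   `size` (um^2), `max_speed` (nm/s), `contact_proportion`,
#'   `n_contacting`.
#' @export
read_s1_table <- function(path) {
  if (dir.exists(path)) {
    kin_raw <- read_s1_sheet(file.path(path, "kinetics.csv"), "Kinetics")
    con_raw <- read_s1_sheet(file.path(path, "contacts.csv"), "Contacts")
  } else if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    kin_raw <- read_s1_sheet(path, "Kinetics")
    con_raw <- read_s1_sheet(path, "Contacts")
  } else {
    stop("expected a directory with kinetics.csv/contacts.csv or an .xlsx ",
         "file with 'Kinetics' and 'Contacts' sheets: ", path)
  }
  to_long <- function(raw, wanted) {
    norm <- normalize_heading(names(raw))
    cond_col <- which(norm %in% c("condition", "group"))
    if (length(cond_col) == 0L) {
      stop("expected a 'Condition' column; got: ",
           paste(names(raw), collapse = ", "))
    }
    cols <- match_headings(names(raw), wanted)
    condition <- as.character(raw[[cond_col[1]]])
    animal <- if (any(norm == "animal")) {
      as.character(raw[[which(norm == "animal")[1]]])
    } else NA_character_
    cell <- if (any(norm %in% c("pr", "cell", "photoreceptor"))) {
      as.character(raw[[which(norm %in% c("pr", "cell", "photoreceptor"))[1]]])
    } else {
      stats::ave(condition, condition, FUN = function(x) {
        paste0("pr", seq_along(x))
      })
    }
    do.call(rbind, lapply(names(cols), function(canon) {
      data.frame(animal_id = animal, cell_id = cell, condition = condition,
                 metric = canon, value = as.numeric(raw[[cols[canon]]]))
    }))
  }
  out <- rbind(
    to_long(kin_raw, c("displacement", "trajectory", "size", "max_speed")),
    to_long(con_raw, c("contact_proportion", "n_contacting"))
  )
  key <- paste(out$animal_id, out$cell_id, out$condition, out$metric)
  if (anyDuplicated(key)) stop("duplicate (animal, cell, metric) records")
  rownames(out) <- NULL
  out
}

#' Grand means of a long-format study table
#'
#' The across-photoreceptor average of each metric over all rows (all
#' conditions pooled), the quantity quoted as the study-wide average of the
#' per-cell values.
#'
#' @param study long table from [read_s1_table()].
#' @param metrics metrics to average (default: all present).
#' @return named numeric vector of grand means.
#' @export
s1_grand_means <- function(study, metrics = unique(study$metric)) {
  vapply(metrics, function(m) {
    mean(study$value[study$metric == m], na.rm = TRUE)
  }, numeric(1))
}
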