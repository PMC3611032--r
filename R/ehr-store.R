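#' Construct a patient record
#'
#' @param patient_id Identifier string.
#' @param sex `"male"` or `"female"`.
#' @param birth_date Birth date (`Date` or `"YYYY-MM-DD"`).
#' @param registered Registration date; defaults to `birth_date` when omitted.
#'   Must not precede `birth_date`.
#' @return A `patient` object.
#' @export
patient <- function(patient_id, sex, birth_date, registered = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  birth_date <- as.Date(birth_date)
  registered <- if (is.null(registered)) birth_date else as.Date(registered)
  if (is.na(birth_date)) stop_ahpdx("schema", "invalid birth_date")
  if (registered < birth_date) {
    stop_ahpdx("schema", "registered date precedes birth date for ", patient_id)
  }
  structure(
    list(patient_id = as.character(patient_id), sex = sex,
         birth_date = birth_date, registered = registered),
    class = "patient"
  )
}

#' Construct a laboratory panel
#'
#' One dated set of analyte measurements (and optional clinical observations)
#' for one patient.
#'
#' @param panel_id Identifier; defaults to `"<patient_id>-<collected>"`.
#' @param patient_id Owning patient's identifier.
#' @param collected Collection date (`Date` or `"YYYY-MM-DD"`).
#' @param analytes Data frame with columns `name`, `value`, `units` (or an
#'   empty data frame). Analyte names must be unique and values finite.
#' @param observations Data frame with columns `name`, `present` (logical);
#'   encodes symptom/clinical-observation factors.
#' @param notes Free-text findings or reminders from the doctor.
#' @return A `lab_panel` object.
#' @export
lab_panel <- function(patient_id, collected, analytes = NULL,
                      observations = NULL, notes = "", panel_id = NULL) {
  collected <- as.Date(collected)
  if (is.na(collected)) stop_ahpdx("schema", "invalid collected date")
  if (is.null(analytes) || nrow(analytes) == 0L) {
    analytes <- data.frame(name = character(), value = numeric(),
                           units = character(), stringsAsFactors = FALSE)
  } else {
    analytes <- data.frame(name = as.character(analytes$name),
                           value = as.numeric(analytes$value),
                           units = as.character(analytes$units),
                           stringsAsFactors = FALSE)
  }
  if (anyDuplicated(analytes$name)) {
    stop_ahpdx("schema", "duplicate analyte in panel: ",
               paste(unique(analytes$name[duplicated(analytes$name)]), collapse = ", "))
  }
  if (any(!is.finite(analytes$value))) {
    stop_ahpdx("schema", "analyte values must be finite")
  }
  if (is.null(observations) || nrow(observations) == 0L) {
    observations <- data.frame(name = character(), present = logical(),
                               stringsAsFactors = FALSE)
  } else {
    observations <- data.frame(name = as.character(observations$name),
                               present = as.logical(observations$present),
                               stringsAsFactors = FALSE)
  }
  patient_id <- as.character(patient_id)
  if (is.null(panel_id)) panel_id <- paste0(patient_id, "-", format(collected))
  structure(
    list(panel_id = as.character(panel_id), patient_id = patient_id,
         collected = collected, analytes = analytes,
         observations = observations, notes = as.character(notes)),
    class = "lab_panel"
  )
}

PANEL_DIALECT <- "ahpdx-panel-1"

#' Parse a laboratory panel from its XML dialect
#'
#' Reads a document in the `ahpdx-panel-1` dialect: root
#' `<panel dialect="ahpdx-panel-1" patient="..." collected="YYYY-MM-DD">`
#' with `<analyte name value units/>` children, optional
#' `<observation name present/>` children and an optional `<notes>` element.
#' Unknown elements are ignored with a warning.
#'
#' @param x XML text, a file path, or an `xml2` document.
#' @return A `lab_panel`.
#' @export
parse_panel_xml <- function(x) {
  doc <- tryCatch(
    if (inherits(x, "xml_document")) x else xml2::read_xml(x),
    error = function(e) stop_ahpdx("parse", "malformed panel XML: ", conditionMessage(e))
  )
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "panel") {
    stop_ahpdx("schema", "root element must be <panel>, got <", xml2::xml_name(root), ">")
  }
  dialect <- xml2::xml_attr(root, "dialect")
  if (!is.na(dialect) && dialect != PANEL_DIALECT) {
    warning("unrecognized panel dialect '", dialect, "'", call. = FALSE)
  }
  need_attr <- function(node, attr, el) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) stop_ahpdx("schema", "<", el, "> missing required attribute '", attr, "'")
    v
  }
  patient_id <- need_attr(root, "patient", "panel")
  collected  <- need_attr(root, "collected", "panel")
  panel_id <- xml2::xml_attr(root, "id")
  if (is.na(panel_id)) panel_id <- NULL

  analytes <- data.frame(name = character(), value = numeric(),
                         units = character(), stringsAsFactors = FALSE)
  observations <- data.frame(name = character(), present = logical(),
                             stringsAsFactors = FALSE)
  notes <- ""
  for (child in xml2::xml_children(root)) {
    nm <- xml2::xml_name(child)
    if (nm == "analyte") {
      value <- suppressWarnings(as.numeric(need_attr(child, "value", "analyte")))
      if (is.na(value)) stop_ahpdx("schema", "non-numeric analyte value")
      units <- xml2::xml_attr(child, "units")
      analytes[nrow(analytes) + 1L, ] <-
        list(need_attr(child, "name", "analyte"), value,
             if (is.na(units)) "" else units)
    } else if (nm == "observation") {
      observations[nrow(observations) + 1L, ] <-
        list(need_attr(child, "name", "observation"),
             tolower(need_attr(child, "present", "observation")) == "true")
    } else if (nm == "notes") {
      notes <- xml2::xml_text(child)
    } else {
      warning("ignoring unknown panel element <", nm, ">", call. = FALSE)
    }
  }
  lab_panel(patient_id = patient_id, collected = collected,
            analytes = analytes, observations = observations,
            notes = notes, panel_id = panel_id)
}

#' Serialize a laboratory panel to the XML dialect
#'
#' Emits the canonical `ahpdx-panel-1` document: analytes sorted by name so
#' output is deterministic, text content XML-escaped. `parse_panel_xml()` of
#' the output reproduces the panel.
#'
#' @param panel A `lab_panel`.
#' @return XML as a single character string.
#' @export
write_panel_xml <- function(panel) {
  stopifnot(inherits(panel, "lab_panel"))
  doc <- xml2::xml_new_root(
    "panel", dialect = PANEL_DIALECT, id = panel$panel_id,
    patient = panel$patient_id, collected = format(panel$collected)
  )
  an <- panel$analytes
  for (i in order(an$name)) {
    xml2::xml_add_child(doc, "analyte", name = an$name[i],
                        value = format(an$value[i], digits = 15),
                        units = an$units[i])
  }
  ob <- panel$observations
  for (i in order(ob$name)) {
    xml2::xml_add_child(doc, "observation", name = ob$name[i],
                        present = if (ob$present[i]) "true" else "false")
  }
  if (nzchar(panel$notes)) {
    xml2::xml_add_child(doc, "notes", panel$notes)
  }
  as.character(doc)
}

# ---- single-file record store ------------------------------------------------
# Line-delimited JSON, one record per line: {"type":"patient"|"panel", ...}.
# Keyed by patient_id (patients) and (patient_id, panel_id) (panels).

#' Open (or create) a record store
#'
#' The store is a single line-delimited JSON file holding patient and panel
#' records. Re-inserting an identical record is a no-op; inserting a
#' conflicting record under an existing key is rejected.
#'
#' @param path File path; created empty if absent.
#' @return An `ahpdx_store` handle.
#' @export
panel_store <- function(path) {
  if (!file.exists(path)) file.create(path)
  structure(list(path = path), class = "ahpdx_store")
}

read_store <- function(store) {
  lines <- readLines(store$path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

append_store <- function(store, rec) {
  con <- file(store$path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

panel_to_rec <- function(panel) {
  list(type = "panel", panel_id = panel$panel_id,
       patient_id = panel$patient_id, collected = format(panel$collected),
       xml = write_panel_xml(panel))
}

#' Add a patient to the store
#' @param store An `ahpdx_store`.
#' @param pat A `patient`.
#' @return The store, invisibly.
#' @export
store_add_patient <- function(store, pat) {
  stopifnot(inherits(store, "ahpdx_store"), inherits(pat, "patient"))
  rec <- list(type = "patient", patient_id = pat$patient_id, sex = pat$sex,
              birth_date = format(pat$birth_date),
              registered = format(pat$registered))
  for (ex in read_store(store)) {
    if (identical(ex$type, "patient") && identical(ex$patient_id, rec$patient_id)) {
      if (identical(ex[names(rec)], rec)) return(invisible(store))
      stop_ahpdx("conflict", "patient ", rec$patient_id,
                 " already stored with different fields")
    }
  }
  append_store(store, rec)
  invisible(store)
}

#' Add a lab panel to the store
#' @param store An `ahpdx_store`.
#' @param panel A `lab_panel`.
#' @return The store, invisibly.
#' @export
store_add_panel <- function(store, panel) {
  stopifnot(inherits(store, "ahpdx_store"), inherits(panel, "lab_panel"))
  rec <- panel_to_rec(panel)
  for (ex in read_store(store)) {
    if (identical(ex$type, "panel") &&
        identical(ex$patient_id, rec$patient_id) &&
        identical(ex$panel_id, rec$panel_id)) {
      if (identical(ex$xml, rec$xml)) return(invisible(store))
      stop_ahpdx("conflict", "panel (", rec$patient_id, ", ", rec$panel_id,
                 ") already stored with different content")
    }
  }
  append_store(store, rec)
  invisible(store)
}

#' Fetch a patient from the store
#' @param store An `ahpdx_store`.
#' @param patient_id Identifier.
#' @return A `patient`.
#' @export
store_get_patient <- function(store, patient_id) {
  for (ex in read_store(store)) {
    if (identical(ex$type, "patient") && identical(ex$patient_id, patient_id)) {
      return(patient(ex$patient_id, ex$sex, ex$birth_date, ex$registered))
    }
  }
  stop_ahpdx("not_found", "unknown patient: ", patient_id)
}

#' List a patient's panels in chronological order
#'
#' @param store An `ahpdx_store`.
#' @param patient_id Identifier; must exist in the store (as a patient record
#'   or as the owner of at least one panel).
#' @return List of `lab_panel` objects, newest collection date first; ties
#'   broken by `panel_id` ascending.
#' @export
list_panels <- function(store, patient_id) {
  recs <- read_store(store)
  known <- any(vapply(recs, function(r) identical(r$patient_id, patient_id), logical(1)))
  if (!known) stop_ahpdx("not_found", "unknown patient: ", patient_id)
  panels <- Filter(function(r) identical(r$type, "panel") &&
                     identical(r$patient_id, patient_id), recs)
  panels <- lapply(panels, function(r) parse_panel_xml(r$xml))
  if (length(panels) == 0L) return(panels)
  dates <- as.Date(vapply(panels, function(p) format(p$collected), character(1)))
  ids <- vapply(panels, function(p) p$panel_id, character(1))
  panels[order(dates, xtfrm(ids), decreasing = c(TRUE, FALSE), method = "radix")]
}
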