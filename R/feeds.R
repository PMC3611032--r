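#' RSS feed configuration
#'
#' @param title Channel title.
#' @param link Channel link URL.
#' @param description Channel description.
#' @param max_items Maximum number of items emitted; at least 1.
#' @return A `feed_config`.
#' @export
feed_config <- function(title, link, description, max_items = 20L) {
  if (max_items < 1L) stop_ahpdx("invalid_profile", "max_items must be >= 1")
  structure(list(title = title, link = link, description = description,
                 max_items = as.integer(max_items)),
            class = "feed_config")
}

# RFC-822 date in GMT as RSS 2.0 requires; C locale so day/month names are
# English regardless of the session locale.
rfc822 <- function(ts) {
  old <- Sys.getlocale("LC_TIME")
  on.exit(suppressWarnings(Sys.setlocale("LC_TIME", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_TIME", "C"))
  format(as.POSIXct(ts, tz = "UTC"), "%a, %d %b %Y %H:%M:%S GMT", tz = "UTC")
}

event_guid <- function(ev) {
  paste("ahpdx", ev$kind, ev$patient_id, ev$ref,
        format(as.POSIXct(ev$timestamp, tz = "UTC"), "%Y%m%dT%H%M%S"),
        sep = ":")
}

event_title <- function(ev) {
  switch(ev$kind,
         new_result = "New medical test results are ready",
         diagnosis  = "A diagnosis update is available",
         critical   = "Important: please contact your doctor")
}

#' Build an RSS 2.0 feed from notification events
#'
#' Emits a valid RSS 2.0 document with one item per event, newest first,
#' truncated to `max_items`. Each item carries a title, `pubDate` (RFC-822,
#' GMT) and a stable `guid` derived from the event's identifiers, so
#' rebuilding the feed from the same events yields the same guids. Item
#' titles never carry numeric scores or analyte values: feeds are an
#' unauthenticated notification channel, so clinical detail stays in the
#' record store.
#'
#' @param config A `feed_config`.
#' @param events List of `notification_event` objects.
#' @return RSS XML as a single character string.
#' @export
build_feed <- function(config, events) {
  stopifnot(inherits(config, "feed_config"))
  if (length(events) > 0L) {
    ts <- vapply(events, function(e) as.numeric(as.POSIXct(e$timestamp, tz = "UTC")),
                 numeric(1))
    events <- events[order(ts, decreasing = TRUE)]
    events <- events[seq_len(min(length(events), config$max_items))]
  }
  doc <- xml2::xml_new_root("rss", version = "2.0")
  ch <- xml2::xml_add_child(doc, "channel")
  xml2::xml_add_child(ch, "title", config$title)
  xml2::xml_add_child(ch, "link", config$link)
  xml2::xml_add_child(ch, "description", config$description)
  for (ev in events) {
    it <- xml2::xml_add_child(ch, "item")
    xml2::xml_add_child(it, "title", event_title(ev))
    xml2::xml_add_child(it, "description",
                        if (nzchar(ev$summary)) ev$summary else event_title(ev))
    xml2::xml_add_child(it, "pubDate", rfc822(ev$timestamp))
    g <- xml2::xml_add_child(it, "guid", event_guid(ev))
    xml2::xml_set_attr(g, "isPermaLink", "false")
  }
  as.character(doc)
}
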