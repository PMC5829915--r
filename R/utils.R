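# internal I/O and logging helpers

# CSV with '#'-prefixed provenance comments before the header
write_csv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_commented <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

log_level <- function() {
  lv <- getOption("nm2motility.log_level", "WARNING")
  match(lv, c("DEBUG", "INFO", "WARNING"), nomatch = 3L)
}

log_info <- function(...) {
  if (log_level() <= 2L) message("[INFO] ", sprintf(...))
  invisible(NULL)
}
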