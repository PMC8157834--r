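# Condition helpers. Every user-facing failure is a classed condition so the
# command-line wrapper can map it to an exit code (usage -> 1, data -> 2).

stop_io <- function(msg, ...) {
  abort(msg, class = c("asvpost_io_error", "asvpost_error"), ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = c("asvpost_format_error", "asvpost_error"), ...)
}

stop_consistency <- function(msg, ...) {
  abort(msg, class = c("asvpost_consistency_error", "asvpost_error"), ...)
}

stop_precondition <- function(msg, ...) {
  abort(msg, class = c("asvpost_precondition_error", "asvpost_error"), ...)
}

# Quote a field for CSV output only when it needs it.
csv_field <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

# Write lines with Unix endings and UTF-8 regardless of platform.
write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
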