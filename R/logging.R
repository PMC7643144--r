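# Structured operation logging. Counting operations are additionally
# appended to Counts/Counting_log.txt so that operator interventions can be
# reviewed later.

#' Set or query the global log file
#'
#' @param path log file path, or `NULL` to disable file logging.
#' @return previous setting, invisibly.
#' @export
set_log_file <- function(path) {
  old <- getOption("colocbox.log_file")
  options(colocbox.log_file = path)
  invisible(old)
}

coloc_log <- function(fmt, ..., level = "INFO", file = NULL) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, sprintf(fmt, ...))
  file <- file %||% getOption("colocbox.log_file")
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  invisible(line)
}

# append a counting operation to <dir>/Counting_log.txt
counting_log <- function(counts_dir, fmt, ...) {
  dir.create(counts_dir, showWarnings = FALSE, recursive = TRUE)
  coloc_log(fmt, ..., file = file.path(counts_dir, "Counting_log.txt"))
}
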