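## internal helpers

## rbind a list of data.frames, ignoring NULLs; NULL when nothing remains
.rbindRows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
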