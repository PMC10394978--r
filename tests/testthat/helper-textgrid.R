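# Hand-written TextGrid fixtures (both text dialects), written to temp files
# at test time. Content: one interval tier "syl" with intervals
# (0, 0.1, "A"), (0.1, 0.2, ""), (0.2, 0.35, "B") and a point tier "events".

textgrid_long <- function(intervals = NULL) {
  if (is.null(intervals))
    intervals <- list(c(0, 0.1, "A"), c(0.1, 0.2, ""), c(0.2, 0.35, "B"))
  iv <- vapply(seq_along(intervals), function(i) {
    z <- intervals[[i]]
    sprintf(paste0("        intervals [%d]:\n",
                   "            xmin = %s\n",
                   "            xmax = %s\n",
                   "            text = \"%s\"\n"), i, z[1], z[2], z[3])
  }, character(1))
  xmax <- intervals[[length(intervals)]][2]
  paste0(
    "File type = \"ooTextFile\"\n",
    "Object class = \"TextGrid\"\n\n",
    "xmin = 0\n",
    sprintf("xmax = %s\n", xmax),
    "tiers? <exists>\n",
    "size = 2\n",
    "item []:\n",
    "    item [1]:\n",
    "        class = \"IntervalTier\"\n",
    "        name = \"syl\"\n",
    "        xmin = 0\n",
    sprintf("        xmax = %s\n", xmax),
    sprintf("        intervals: size = %d\n", length(intervals)),
    paste(iv, collapse = ""),
    "    item [2]:\n",
    "        class = \"TextTier\"\n",
    "        name = \"events\"\n",
    "        xmin = 0\n",
    sprintf("        xmax = %s\n", xmax),
    "        points: size = 1\n",
    "        points [1]:\n",
    "            number = 0.05\n",
    "            mark = \"click\"\n")
}

textgrid_short <- function() {
  paste0(
    "File type = \"ooTextFile\"\n",
    "Object class = \"TextGrid\"\n\n",
    "0\n0.35\n<exists>\n2\n",
    "\"IntervalTier\"\n\"syl\"\n0\n0.35\n3\n",
    "0\n0.1\n\"A\"\n",
    "0.1\n0.2\n\"\"\n",
    "0.2\n0.35\n\"B\"\n",
    "\"TextTier\"\n\"events\"\n0\n0.35\n1\n",
    "0.05\n\"click\"\n")
}

write_fixture <- function(content, ext = ".TextGrid") {
  path <- tempfile(fileext = ext)
  writeLines(content, path, sep = "")
  path
}
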