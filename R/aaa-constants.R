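#' GI segment names, oral-to-anal order
#'
#' The six lumped segments of the transit chain: stomach, duodenum,
#' jejunum, ileum, colon, rectum.
#' @export
gi_segment_names <- c("stomach", "duodenum", "jejunum", "ileum",
                      "colon", "rectum")
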