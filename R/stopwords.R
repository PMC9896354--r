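#' Default English stopword list
#'
#' A standard snowball-style English stopword list used by [tokenize()] when
#' no explicit list is supplied.  Stopwords are removed *before* N-gram
#' extraction, so bigrams and trigrams can span removed stopwords; lexicon
#' files must be built under the same convention.  Apostrophes are stripped
#' by the tokenizer, so contracted forms appear here without them
#' ("dont", "isnt").
#'
#' @return Character vector of lowercase stopwords.
#' @export
#' @examples
#' head(default_stopwords())
default_stopwords <- function() {
  c(
    "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "yourself", "yourselves", "he", "him", "his",
    "himself", "she", "her", "hers", "herself", "it", "its", "itself",
    "they", "them", "their", "theirs", "themselves", "what", "which",
    "who", "whom", "this", "that", "these", "those", "am", "is", "are",
    "was", "were", "be", "been", "being", "have", "has", "had", "having",
    "do", "does", "did", "doing", "a", "an", "the", "and", "but", "if",
    "or", "because", "as", "until", "while", "of", "at", "by", "for",
    "with", "about", "against", "between", "into", "through", "during",
    "before", "after", "above", "below", "to", "from", "up", "down",
    "in", "out", "on", "off", "over", "under", "again", "further",
    "then", "once", "here", "there", "when", "where", "why", "how",
    "all", "any", "both", "each", "few", "more", "most", "other",
    "some", "such", "no", "nor", "not", "only", "own", "same", "so",
    "than", "too", "very", "s", "t", "can", "will", "just", "don",
    "dont", "should", "now", "isnt", "arent", "wasnt", "werent",
    "couldnt", "wouldnt", "shouldnt", "im", "ive", "id", "youre",
    "youve", "hes", "shes", "thats", "whats", "cant", "didnt",
    "doesnt", "hasnt", "havent", "lets", "wont"
  )
}
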