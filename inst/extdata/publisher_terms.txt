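# Boilerplate terms inserted into abstracts by publishers (copyright lines,
# rights statements).  Placeholder defaults; extend per corpus.
copyright
elsevier
wiley
springer
rights
reserved
author
authors
publisher
publishers
licensee
ltd
inc
verlag
bv
abstract
crossref
doi
issn
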