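# Birth-defect keyword vocabulary (one whole-token term per line; matching
# is case-insensitive, with hyphen and space interchangeable in multi-word
# terms). Editable: the list is a transparent stand-in for trained
# defect-detection classifiers.
birth defect
birth defects
congenital
craniosynostosis
spina bifida
cleft lip
cleft palate
heart defect
heart murmur
gastroschisis
anencephaly
hypospadias
microcephaly
hydrocephalus
clubfoot
club foot
hip dysplasia
omphalocele
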