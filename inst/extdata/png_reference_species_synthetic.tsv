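species
Abelmoschus manihot
Acalypha grandis
Acalypha wilkesiana
Ageratum conyzoides
Albizia procera
Albizia saman
Allophylus cobbe
Alocasia cucullata
Alphitonia incana
Alstonia scholaris
Amomum aculeatum
Angiopteris evecta
Areca catechu
Artocarpus altilis
Asplenium nidus
Barringtonia asiatica
Bidens pilosa
Bixa orellana
Bryophyllum pinnatum
Callicarpa longifolia
Calophyllum inophyllum
Calotropis gigantea
Carica papaya
Caryota rumphiana
Cassia alata
Casuarina equisetifolia
Cerbera floribunda
Cheilocostus speciosus
Cocos nucifera
Codiaeum variegatum
Cordyline fruticosa
Crinum asiaticum
Cycas circinalis
Cymbopogon citratus
Dendrocnide cordata
Dendrocnide latifolia
Dioscorea bulbifera
Donax canniformis
Dracaena angustifolia
Elaeocarpus sphaericus
Elatostema sp
Epipremnum pinnatum
Euodia hortensis
Euphorbia heterophylla
Euphorbia hirta
Euphorbia plumerioides
Euphorbia tithymaloides
Ficus adenosperma
Ficus pungens
Ficus septica
Ficus wassa
Gnetum gnemon
Gnetum gnemonoides
Gymnostoma papuanum
Hemigraphis reptans
Hibiscus rosa-sinensis
Homalium foetidum
Ipomoea pes-caprae
Kalanchoe pinnata
Laportea decumana
Laportea interrupta
Leucosyke capitellata
Macaranga clavata
Macaranga darbyshirei
Maclura cochinchinensis
Mangifera indica
Manihot esculenta
Melanolepis multiglandulosa
Melicope triphylla
Merremia peltata
Metroxylon sagu
Mimosa pudica
Morinda citrifolia
Mucuna novo-guineensis
Murraya paniculata
Musa acuminata
Nauclea orientalis
Neonauclea purpurea
Nephrolepis hirsutula
Nicotiana tabacum
Ocimum basilicum
Octomeles sumatrana
Pandanus dubius
Pangium edule
Passiflora foetida
Peperomia pellucida
Phyllanthus amarus
Phyllanthus niruri
Pimelodendron amboinicum
Piper betle
Piper mestonii
Piscidia grandifolia
Pisonia longirostris
Plectranthus amboinicus
Plectranthus hereroensis
Plectranthus parviflorus
Plectranthus scutellarioides
Premna serratifolia
Psidium guajava
Pterocarpus indicus
Scaevola sericea
Sida rhombifolia
Solanum torvum
Sphaerostephanos unitus
Spondias dulcis
Stephania japonica
Syzygium malaccense
Tabernaemontana pandacaqui
Uncaria lanosa
Uncaria orientalis
Urticastrum decumanum
Virola surinamensis
Wedelia biflora
Zingiber officinale
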