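>AtH3.2 species=arabidopsis family=H3 variant=H3.2
ARTKQTARKSTGGKAPRKQLATKAARKSAPTTGGVKKPHRYRPGTVALREIRRYQKSTELLIRKLPFQRLVREIAQDFKTDLRFQSAAVKALQEACEAYLVGLFEDTNLCAIHAKRVTIMPKDIQLARRIRGERA
>AtH3.3 species=arabidopsis family=H3 variant=H3.3
ARTKQTARKSTGGKAPRKQLATKAARKSAPTTGGVKKPHRYRPGTVALREIRRYQKSTELLIRKLPFQRLVREIAQDFKTDLRFQSAAIKALQEASEAYLVGLFEDTNLCAIHAKRVTIMPKDIQLARRIRGERA
>AtH4 species=arabidopsis family=H4 variant=H4
SGRGKGGKGLGKGGAKRHRKVLRDNIQGITKPAIRRLARRGGVKRISGLIYEETRGVLKIFLENVIRDAVTRTEHAKRKTVTAMDVVYALKRQGRTLYGFGG
>AtH2B.6 species=arabidopsis family=H2B variant=H2B.6
APKAEKKPAEKKPAAEKPVEEKSKAEKAPAKKRKRSRKESYSVYVYKVLKQVHPDTGISSKAMGIMNSFVNDIFERIAGEASRLAHYNKRSTITSREIQTAVRLLLPGELAKHAVSEGTKAVTKYTSSK
>AtH2B.7 species=arabidopsis family=H2B variant=H2B.7
APKAEKKPAEKKPAAEKPIEEKSKAEKAPAKKRKRSRKESYSVYVYKVLKQVHPDTGISSKAMGIMNSFVNDIFERIAGEASRLAHYNKRSTITSREIQTSVRLLLPGELAKHAVSEGTKAVTKYTSSK
>AtH2B.10 species=arabidopsis family=H2B variant=H2B.10
APKAEKKPAEKKPASEKPVEEKSKAEKAPAKKRKRSRKESYSVYVYKVLKQVHPDTGISSKAMGIMNSFVNDIFERIAGEASRLAHYNKRSTITSREIQTAVRLLLPGELAKHAVSEGTKAVTKYTSSK
>AtH2A.4 species=arabidopsis family=H2A variant=H2A.4
SGRGKQGGKARAKAKTRSSRAGLQFPVGRVHRLLRKGNYAERVGAGAPVYLAAVLEYLTAEILELAGNAARDNKKTRIIPRHLQLAIRNDEELNKLLGKVTIAQGGVLPNIQAVLLPKKTESHHKAKGKAGDSKSSGAQPTASKGD
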