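"id","area_ha","land_class","fertility","dominant_species","origin","mean_diameter_cm","basal_area_m2_ha","volume_m3_ha","age_years","ditch_depth_cm","years_since_dnm","years_since_fertilization","diameter_classes"
"c00001","102378.732795","mineral","sub_xeric","birch","seeded","23.4437906445","21.0096611753","170.898956004",59,"","",32,"1:0.4040417104;3:3.62670662803;5:9.97359256483;7:19.1166898663;9:30.3763269193;11:42.6641580771;13:54.5319905735;15:64.3514873562;17:70.611469169;19:72.2671904664;21:69.0318757307;23:61.4935754428;25:50.9880347045;27:39.2506163802;29:27.965815135;31:18.3786905633;33:11.099188521;35:6.13549218289;37:3.0917890728"
"c00002","84428.784139","drained_peat","xeric","pine","natural","23.4370314113","17.0590942837","138.751632782",63,"60","19",58,"1:0.328590598156;3:2.94944432387;5:8.11101199302;7:15.5462778858;9:24.7019838852;11:34.6922925202;13:44.3386719889;15:52.3163652162;17:57.3965600412;19:58.7307162476;21:56.0876240318;23:49.9479830761;25:41.4002336101;27:31.8566894007;29:22.6867603289;31:14.9011392398;33:8.99338062704;35:4.96789939348;37:2.50142535506"
"c00003","63729.1058203","undrained_peat","sub_xeric","pine","natural","0","0","0",0,"","",47,""
"c00004","36027.215861","drained_peat","sub_xeric","pine","seeded","25.8771901787","22.3171890266","186.992399357",65,"60","37",39,"1:0.262101042595;3:2.35424154249;5:6.49091734262;7:12.5126523018;9:20.084779793;11:28.6582445169;13:37.4712638294;15:45.6056562471;17:52.101183291;19:56.1140174954;21:57.0860375533;23:54.8780570454;25:49.8208670146;27:42.6574932984;29:34.3843274691;31:26.0349486035;33:18.4720010473;35:12.2481550921;37:7.56822825952;39:4.34505924117;41:2.31068800825"
"c00005","24505.4289251","mineral","mesic","spruce","seeded","13.5556780664","17.1286619427","118.213027296",35,"","",63,"1:5.10331697621;3:45.3005940802;5:119.459129945;7:208.565216357;9:280.921640639;11:304.906894236;13:268.978148287;15:191.675834351;17:108.863619431;19:48.4258383744;21:16.5393294143"
"c00006","26075.8382799","mineral","sub_xeric","pine","natural","9.27518902886","16.5318250023","101.793212735",24,"","",37,"1:33.5529093436;3:289.006833368;5:680.372582016;7:922.897974256;9:795.072849205;11:429.822246539;13:139.121103161;15:25.3464206482"
"c00007","16957.2941797","undrained_peat","sub_xeric","birch","natural","0","0","0",0,"","",22,""
"c00008","28297.6","nonforest","sub_xeric","pine","natural","0","0","0",0,"","",60,""
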