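operation_id,location,system,synthetic_fertilizer_used,herbicide_used,fungicide_used,insecticide_used,tillage_used,cover_crop_or_resident_vegetation,field_margins_hedgerows,organic_amendments_used,livestock_integrated,code_fertilizers,code_herbicides,code_fungicides,code_insecticides,code_tillage,code_cover_crops,code_field_margins,code_organic_amendments,code_grazers,composite_printed,erratum
crop01,"Merced, CA",cropland_full,no,no,no,no,yes,yes,yes,yes,no,1,1,1,1,0,1,1,1,0,7,FALSE
crop02,"Butte, CA",cropland_full,no,no,yes,no,no,yes,yes,yes,no,1,1,0,1,1,1,1,1,0,7,FALSE
crop03,"Merced, CA",cropland_full,no,no,no,no,no,yes,yes,yes,no,1,1,1,1,1,1,1,1,0,8,FALSE
crop04,"Merced, CA",cropland_full,no,no,no,no,no,yes,yes,yes,no,1,1,1,1,1,1,1,1,0,8,FALSE
crop05,"Yolo, CA",cropland_full,no,no,yes,no,yes,yes,yes,yes,yes,1,1,0,1,0,1,1,1,1,7,FALSE
crop06,"Butte, CA",cropland_full,yes,yes,yes,yes,no,yes,no,yes,no,0,0,0,0,1,1,0,1,0,3,FALSE
crop07,"Butte, CA",cropland_full,yes,yes,yes,yes,no,no,no,no,no,0,0,0,0,1,0,0,0,0,1,FALSE
crop08,"Yolo, CA",cropland_full,yes,yes,yes,yes,no,no,no,no,no,0,0,0,0,1,0,0,0,0,1,FALSE
crop09,"Yolo, CA",cropland_full,yes,yes,yes,yes,no,no,no,no,no,0,0,0,0,1,0,0,0,0,1,FALSE
crop10,"Butte, CA",cropland_full,no,no,yes,no,no,yes,yes,yes,no,1,1,0,1,1,1,1,1,0,7,FALSE
crop11,"Merced, CA",cropland_full,no,no,yes,no,no,yes,no,yes,no,1,1,0,1,1,1,0,1,0,6,FALSE
crop12,"Merced, CA",cropland_full,yes,yes,yes,yes,no,no,no,no,no,0,0,0,0,1,0,0,0,0,1,FALSE
crop13,"Yolo, CA",cropland_full,no,no,no,no,no,yes,no,no,yes,1,1,1,1,1,1,0,0,1,7,FALSE
crop14,"Merced, CA",cropland_full,yes,yes,yes,yes,no,no,no,yes,no,0,0,0,0,1,0,0,1,0,2,FALSE
crop15,"Merced, CA",cropland_full,yes,yes,yes,yes,no,no,no,yes,no,0,0,0,0,1,0,0,1,0,2,FALSE
crop16,"Merced, CA",cropland_full,yes,yes,yes,yes,no,yes,no,yes,no,0,0,0,0,1,1,0,1,0,3,FALSE
crop17,"Bladen, NE",cropland_corn,yes,yes,,yes,yes,no,,,no,0,0,,0,0,0,,,0,0,FALSE
crop18,"York, NE",cropland_corn,yes,yes,,yes,yes,no,,,no,0,0,,0,0,0,,,0,0,FALSE
crop19,"Bismarck, ND",cropland_corn,yes,yes,,yes,no,no,,,no,0,0,,0,1,0,,,0,1,FALSE
crop20,"Bismarck, ND",cropland_corn,yes,yes,,yes,no,no,,,no,0,0,,0,1,0,,,0,1,FALSE
crop21,"White, SD",cropland_corn,yes,yes,,yes,yes,no,,,no,0,0,,0,0,0,,,0,0,FALSE
crop22,"Pipestone, MN",cropland_corn,yes,yes,,yes,yes,no,,,no,0,0,,0,0,0,,,0,0,FALSE
crop23,"Toronto, SD",cropland_corn,yes,yes,,yes,yes,no,,,no,0,0,,0,0,0,,,0,0,FALSE
crop24,"Gary, SD",cropland_corn,yes,yes,,yes,yes,no,,,no,0,0,,0,0,0,,,0,0,FALSE
crop25,"Arlington, SD",cropland_corn,yes,yes,,yes,yes,no,,,no,0,0,,0,0,0,,,0,0,FALSE
crop26,"Lake Norden, SD",cropland_corn,yes,yes,,yes,yes,no,,,no,0,0,,0,0,0,,,0,0,FALSE
crop27,"Bladen, NE",cropland_corn,no,yes,,no,no,yes,,,no,1,0,,1,1,1,,,0,4,FALSE
crop28,"York, NE",cropland_corn,no,yes,,no,no,yes,,,no,1,0,,1,1,1,,,0,4,FALSE
crop29,"Bismarck, ND",cropland_corn,yes,no,,no,no,yes,,,yes,0,1,,1,1,1,,,1,5,FALSE
crop30,"Bismarck, ND",cropland_corn,no,yes,,no,no,yes,,,yes,1,0,,1,1,1,,,1,5,FALSE
crop31,"White, SD",cropland_corn,no,no,,no,yes,yes,,,no,1,1,,1,0,1,,,0,4,FALSE
crop32,"Pipestone, MN",cropland_corn,no,no,,no,yes,yes,,,no,1,1,,1,0,1,,,0,4,FALSE
crop33,"Toronto, SD",cropland_corn,no,yes,,yes,no,yes,,,no,1,0,,0,1,1,,,0,3,FALSE
crop34,"Gary, SD",cropland_corn,no,no,,no,yes,yes,,,no,1,1,,1,0,1,,,0,4,TRUE
crop35,"Arlington, SD",cropland_corn,no,yes,,no,no,yes,,,yes,1,0,,1,1,1,,,1,5,FALSE
crop36,"Lake Norden, SD",cropland_corn,no,yes,,no,no,yes,,,no,1,0,,1,1,1,,,0,4,FALSE
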